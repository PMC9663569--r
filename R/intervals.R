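#' Genomic intervals as tibbles
#'
#' All coordinates in this package are 0-based, half-open (BED-native):
#' an interval covers bases `start, start+1, ..., end-1`. Strand is one of
#' `"+"`, `"-"` or `"*"` (unstranded). Conversions to the 1-based closed
#' convention happen only at the GenomicRanges boundary, internally.
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Numeric 0-based half-open coordinates, `start < end`.
#' @param strand Strand, recycled; `"."` is accepted as unstranded.
#' @param ... Further columns carried along (e.g. `gene_id`), tidy-style.
#' @return A tibble with columns `chrom`, `start`, `end`, `strand`, plus `...`.
#' @examples
#' gintervals("chr1", 0, 100)
#' @export
gintervals <- function(chrom, start, end, strand = "*", ...) {
  strand <- normalise_strand(strand)
  out <- tibble::tibble(chrom = as.character(chrom),
                        start = as.numeric(start),
                        end = as.numeric(end),
                        strand = strand, ...)
  validate_intervals(out)
  out
}

#' @noRd
normalise_strand <- function(strand) {
  strand <- as.character(strand)
  strand[strand == "." | is.na(strand)] <- "*"
  strand[strand == "−"] <- "-"
  bad <- !strand %in% c("+", "-", "*")
  if (any(bad)) stop("invalid strand value(s): ", paste(unique(strand[bad]), collapse = ", "))
  strand
}

#' Validate an interval tibble
#'
#' Checks the half-open invariants (`0 <= start < end`) and, when a genome is
#' supplied, that every interval lies on a known chromosome and within its
#' length.
#'
#' @param x An interval tibble.
#' @param genome Optional genome tibble ([as_genome()]).
#' @return `x`, invisibly, after validation.
#' @export
validate_intervals <- function(x, genome = NULL) {
  stopifnot(is.data.frame(x), all(c("chrom", "start", "end") %in% names(x)))
  bad <- which(!(x$start >= 0 & x$start < x$end))
  if (length(bad)) {
    stop("invalid interval(s) (need 0 <= start < end) at row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  if (!is.null(genome)) {
    size <- genome_size_of(genome, x$chrom)
    over <- which(x$end > size)
    if (length(over)) {
      stop("interval(s) beyond chromosome end at row(s): ",
           paste(utils::head(over, 5), collapse = ", "))
    }
  }
  invisible(x)
}

#' @noRd
to_gr <- function(x) {
  strand <- if ("strand" %in% names(x)) x$strand else "*"
  GenomicRanges::GRanges(seqnames = x$chrom,
                         ranges = IRanges::IRanges(start = x$start + 1, end = x$end),
                         strand = strand)
}

#' @noRd
from_gr <- function(gr) {
  tibble::tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
                 start = GenomicRanges::start(gr) - 1,
                 end = as.numeric(GenomicRanges::end(gr)),
                 strand = as.character(GenomicRanges::strand(gr)))
}

#' Base pairs shared by two intervals
#'
#' Element-wise overlap in bp between intervals of `a` and `b` (recycled to a
#' common length). Intervals on different chromosomes share 0 bp; adjacency
#' under the half-open convention is 0 bp.
#'
#' @param a,b Interval tibbles (rows paired element-wise).
#' @return Numeric vector of non-negative bp counts.
#' @examples
#' overlap_bp(gintervals("chr1", 100, 200), gintervals("chr1", 150, 300))
#' @export
overlap_bp <- function(a, b) {
  n <- max(nrow(a), nrow(b))
  ai <- rep_len(seq_len(nrow(a)), n); bi <- rep_len(seq_len(nrow(b)), n)
  raw <- pmin(a$end[ai], b$end[bi]) - pmax(a$start[ai], b$start[bi])
  ifelse(a$chrom[ai] == b$chrom[bi], pmax(0, raw), 0)
}

#' Merge intervals into disjoint unions
#'
#' Collapses a set of intervals into sorted, pairwise-disjoint regions covering
#' exactly the same base pairs; book-ended (adjacent) intervals are merged.
#' Strand is ignored and the result is unstranded.
#'
#' @param x Interval tibble.
#' @return Interval tibble of merged regions, sorted by chromosome and start.
#' @export
merge_intervals <- function(x) {
  if (nrow(x) == 0) return(gintervals(character(), numeric(), numeric()))
  gr <- GenomicRanges::reduce(to_gr(x), ignore.strand = TRUE)
  out <- from_gr(GenomicRanges::sort(gr, ignore.strand = TRUE))
  out$strand <- "*"
  out
}

#' Randomly relocate intervals across a genome
#'
#' Each interval keeps its length and is placed uniformly over all valid start
#' positions. By default the destination chromosome is drawn with probability
#' proportional to the number of valid placements it offers (its capacity for
#' that length); `same_chrom = TRUE` restricts placement to the interval's own
#' chromosome. Reproducible for a fixed seed.
#'
#' @param x Interval tibble.
#' @param genome Genome tibble.
#' @param seed Integer seed.
#' @param same_chrom Keep each interval on its original chromosome?
#' @return Interval tibble with the same lengths (and extra columns) as `x`.
#' @export
shuffle_intervals <- function(x, genome, seed, same_chrom = FALSE) {
  if (nrow(x) == 0) return(x)
  withr::with_seed(seed, shuffle_intervals_impl(x, genome, same_chrom))
}

#' @noRd
row_cumsum <- function(m) {
  if (ncol(m) > 1) for (j in 2:ncol(m)) m[, j] <- m[, j - 1] + m[, j]
  m
}

#' @noRd
shuffle_intervals_impl <- function(x, genome, same_chrom = FALSE) {
  if (nrow(x) == 0) return(x)
  len <- x$end - x$start
  if (same_chrom) {
    size <- genome_size_of(genome, x$chrom)
    bad <- which(len > size)
    if (length(bad)) {
      stop("interval at row ", bad[1], " (", x$chrom[bad[1]], ":", x$start[bad[1]],
           "-", x$end[bad[1]], ") is longer than its chromosome")
    }
    cap <- size - len + 1
    new_chrom <- x$chrom
  } else {
    # capacity matrix: rows intervals, cols chromosomes
    cap_mat <- outer(len, genome$size, function(l, s) pmax(0, s - l + 1))
    tot <- rowSums(cap_mat)
    bad <- which(tot == 0)
    if (length(bad)) {
      stop("interval at row ", bad[1], " (", x$chrom[bad[1]], ":", x$start[bad[1]],
           "-", x$end[bad[1]], ") is longer than every chromosome")
    }
    cum <- row_cumsum(cap_mat)
    u <- stats::runif(nrow(x)) * tot
    ci <- rowSums(cum < u) + 1
    new_chrom <- genome$chrom[ci]
    cap <- cap_mat[cbind(seq_len(nrow(x)), ci)]
  }
  new_start <- pmin(floor(stats::runif(nrow(x)) * cap), cap - 1)
  out <- x
  out$chrom <- new_chrom
  out$start <- new_start
  out$end <- new_start + len
  out
}
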