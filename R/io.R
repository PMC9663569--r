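#' Read a BED file of intervals
#'
#' Accepts >= 3 tab-separated columns (chrom, start, end); column 4 is kept as
#' `name` when present, and strand is parsed from column 6 (`.` meaning
#' unstranded). Lines failing the half-open invariant are rejected with their
#' line number.
#'
#' @param path Path to a BED file.
#' @return Interval tibble; with a `name` column when the file has one.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(gintervals(character(), numeric(), numeric()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(fields)
  if (any(ncol < 3)) {
    stop("malformed BED line (fewer than 3 columns) at line ", which(ncol < 3)[1])
  }
  chrom <- vapply(fields, `[[`, "", 1)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) stop("unparseable coordinates at line ", bad[1])
  bad <- which(!(start >= 0 & start < end))
  if (length(bad)) stop("invalid interval (need 0 <= start < end) at line ", bad[1])
  name <- ifelse(ncol >= 4, vapply(fields, function(f) f[min(4, length(f))], ""), NA)
  strand <- ifelse(ncol >= 6, vapply(fields, function(f) f[min(6, length(f))], ""), "*")
  out <- gintervals(chrom, start, end, strand = normalise_strand(strand))
  if (any(ncol >= 4)) out$name <- name
  out
}

#' Write intervals as BED
#'
#' @param x Interval tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  name <- if ("name" %in% names(x)) x$name else if ("gene_id" %in% names(x)) x$gene_id else "."
  strand <- if ("strand" %in% names(x)) x$strand else "*"
  strand <- ifelse(strand == "*", ".", strand)
  df <- data.frame(x$chrom, format_coord(x$start), format_coord(x$end),
                   name, 0, strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @noRd
format_coord <- function(x) format(x, scientific = FALSE, trim = TRUE)

#' Read a BEDPE file of loops
#'
#' Expects >= 6 columns (`chr1 s1 e1 chr2 s2 e2`) with optional trailing
#' statistics; following the FitHiChIP convention the last extra column, when
#' present, is taken as the interaction q-value. Trans (inter-chromosomal)
#' rows are skipped with a warning giving their count; anchors are put in
#' canonical left-before-right order.
#'
#' @param path Path to a BEDPE file.
#' @param label Differential-loop label to attach to every loop read
#'   (`"none"`, `"overinteracting"` or `"underinteracting"`).
#' @return Loop tibble ([gloops()]).
#' @export
read_bedpe_loops <- function(path, label = "none") {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(gloops(character(), numeric(), numeric(), numeric(), numeric()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(fields)
  if (any(ncol < 6)) {
    stop("malformed BEDPE line (fewer than 6 columns) at line ", which(ncol < 6)[1])
  }
  col <- function(i) vapply(fields, `[[`, "", i)
  num <- function(i, what) {
    v <- suppressWarnings(as.numeric(col(i)))
    if (anyNA(v)) stop("unparseable ", what, " at line ", which(is.na(v))[1])
    v
  }
  chr1 <- col(1); chr2 <- col(4)
  s1 <- num(2, "coordinate"); e1 <- num(3, "coordinate")
  s2 <- num(5, "coordinate"); e2 <- num(6, "coordinate")
  qvalue <- rep(NA_real_, length(lines))
  extra <- ncol > 6
  if (any(extra)) {
    qvalue[extra] <- suppressWarnings(as.numeric(
      vapply(fields[extra], function(f) f[[length(f)]], "")))
  }
  cis <- chr1 == chr2
  if (any(!cis)) {
    warning(sum(!cis), " trans interaction(s) skipped in ", basename(path))
  }
  gloops(chr1[cis], s1[cis], e1[cis], s2[cis], e2[cis],
         qvalue = qvalue[cis], label = label)
}

#' Write loops as BEDPE
#'
#' @param loops Loop tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedpe <- function(loops, path) {
  df <- data.frame(loops$chrom, format_coord(loops$start1), format_coord(loops$end1),
                   loops$chrom, format_coord(loops$start2), format_coord(loops$end2),
                   ifelse(is.na(loops$qvalue), ".", format(loops$qvalue, trim = TRUE)))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph signal track
#'
#' A track is a partition: sorted, non-overlapping scored intervals; any base
#' not covered by a record has value 0. Overlapping records are an error.
#'
#' @param path Path to a 4-column bedGraph file.
#' @return A track tibble (`chrom, start, end, value`), sorted.
#' @export
read_bedgraph <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "track")]
  if (length(lines) == 0) {
    return(tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric(), value = numeric()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 4)) {
    stop("malformed bedGraph line at line ", which(lengths(fields) < 4)[1])
  }
  out <- tibble::tibble(chrom = vapply(fields, `[[`, "", 1),
                        start = as.numeric(vapply(fields, `[[`, "", 2)),
                        end = as.numeric(vapply(fields, `[[`, "", 3)),
                        value = as.numeric(vapply(fields, `[[`, "", 4)))
  if (anyNA(out$start) || anyNA(out$end) || anyNA(out$value)) {
    stop("unparseable bedGraph record in ", basename(path))
  }
  as_track(out)
}

#' Validate and sort a signal-track tibble
#'
#' @param x Tibble with columns `chrom, start, end, value`.
#' @return Sorted track tibble; errors if records overlap (partition contract).
#' @export
as_track <- function(x) {
  stopifnot(all(c("chrom", "start", "end", "value") %in% names(x)))
  out <- dplyr::arrange(tibble::as_tibble(x), .data$chrom, .data$start)
  validate_intervals(out)
  same <- out$chrom[-1] == out$chrom[-nrow(out)]
  if (nrow(out) > 1 && any(same & out$start[-1] < out$end[-nrow(out)])) {
    stop("overlapping bedGraph records: a signal track must be a partition")
  }
  out[c("chrom", "start", "end", "value")]
}

#' Write a track as bedGraph
#'
#' @param track Track tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  df <- data.frame(track$chrom, format_coord(track$start), format_coord(track$end),
                   format(track$value, trim = TRUE, scientific = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Mean track signal over intervals
#'
#' Per-bp mean of a signal track over each query interval, counting uncovered
#' bases as 0 (bedGraph semantics).
#'
#' @param track Track tibble.
#' @param intervals Interval tibble of queries.
#' @return Numeric vector of means, one per query.
#' @export
track_mean <- function(track, intervals) {
  out <- numeric(nrow(intervals))
  by_chrom <- split(seq_len(nrow(track)), track$chrom)
  for (cname in unique(intervals$chrom)) {
    sel <- which(intervals$chrom == cname)
    rows <- by_chrom[[cname]]
    if (is.null(rows)) next
    st <- track$start[rows]; en <- track$end[rows]; val <- track$value[rows]
    # integral of the step function up to each record boundary
    area <- cumsum(val * (en - st))
    integral_to <- function(pos) {
      i <- findInterval(pos, st)
      base <- ifelse(i >= 1, area[pmax(i, 1)], 0)
      # subtract the part of record i beyond pos (if pos falls inside it)
      inside <- i >= 1 & pos < en[pmax(i, 1)]
      base - ifelse(inside, val[pmax(i, 1)] * (en[pmax(i, 1)] - pos), 0)
    }
    tot <- integral_to(intervals$end[sel]) - integral_to(intervals$start[sel])
    out[sel] <- tot / (intervals$end[sel] - intervals$start[sel])
  }
  out
}

#' Track value at single positions
#'
#' @param track Track tibble.
#' @param chrom,pos Vectors of chromosome and 0-based position.
#' @return Numeric vector of values (0 where uncovered).
#' @export
track_value_at <- function(track, chrom, pos) {
  out <- numeric(length(pos))
  by_chrom <- split(seq_len(nrow(track)), track$chrom)
  for (cname in unique(chrom)) {
    sel <- which(chrom == cname)
    rows <- by_chrom[[cname]]
    if (is.null(rows)) next
    st <- track$start[rows]; en <- track$end[rows]; val <- track$value[rows]
    i <- findInterval(pos[sel], st)
    hit <- i >= 1 & pos[sel] < en[pmax(i, 1)]
    out[sel] <- ifelse(hit, val[pmax(i, 1)], 0)
  }
  out
}

#' Read a per-gene expression table
#'
#' Expects a header with `gene_id`, `wt_count`, `ko_count`, `log2fc` and
#' (optionally) `fdr`. Counts are normalised (library-size corrected)
#' condition-level values; `fdr` may be missing or `NA`.
#'
#' @param path Path to a TSV file.
#' @return Tibble keyed by `gene_id`.
#' @export
read_expression_table <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("gene_id", "wt_count", "ko_count", "log2fc")
  miss <- setdiff(need, names(out))
  if (length(miss)) stop("expression table misses column(s): ",
                         paste(miss, collapse = ", "))
  if (!"fdr" %in% names(out)) out$fdr <- NA_real_
  if (anyDuplicated(out$gene_id)) {
    stop("duplicate gene_id in expression table: ",
         out$gene_id[duplicated(out$gene_id)][1])
  }
  if (any(out$wt_count < 0 | out$ko_count < 0, na.rm = TRUE)) {
    stop("negative counts in expression table")
  }
  bad_fdr <- !is.na(out$fdr) & (out$fdr < 0 | out$fdr > 1)
  if (any(bad_fdr)) stop("fdr outside [0, 1] in expression table")
  out
}

#' Read a gene annotation BED
#'
#' BED with gene identifiers in column 4 and strand in column 6.
#'
#' @param path Path to a BED file.
#' @return Gene tibble (`chrom, start, end, strand, gene_id`).
#' @export
read_genes_bed <- function(path) {
  x <- read_bed(path)
  if (!"name" %in% names(x)) stop("gene BED needs identifiers in column 4")
  dplyr::rename(x, gene_id = "name")
}
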