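# Internal vectorised overlap machinery.
#
# The permutation null runs hundreds of thousands of shuffle-and-count rounds,
# so boolean overlap queries are answered against a pre-merged, sorted subject
# index with findInterval() rather than building a GRanges per round. The
# GenomicRanges route remains the reference for all non-hot-path operations
# and the two are cross-checked in the test suite.

#' @noRd
subject_index <- function(subject) {
  merged <- merge_intervals(subject)
  lapply(split(merged[c("start", "end")], merged$chrom),
         function(d) list(starts = d$start, ends = d$end))
}

# logical: does each query interval overlap >= 1 bp of the indexed subject?
#' @noRd
overlaps_any_idx <- function(chrom, start, end, idx) {
  hits <- logical(length(chrom))
  for (cname in intersect(unique(chrom), names(idx))) {
    sel <- which(chrom == cname)
    st <- idx[[cname]]$starts; en <- idx[[cname]]$ends
    i <- findInterval(start[sel], st)
    left <- i >= 1 & en[pmax(i, 1)] > start[sel]
    nxt <- pmin(i + 1, length(st))
    right <- i < length(st) & st[nxt] < end[sel]
    hits[sel] <- left | right
  }
  hits
}

#' Does each interval of A overlap any interval of B?
#'
#' @param a,b Interval tibbles.
#' @return Logical vector, one element per row of `a`.
#' @export
overlaps_any <- function(a, b) {
  if (nrow(b) == 0) return(rep(FALSE, nrow(a)))
  overlaps_any_idx(a$chrom, a$start, a$end, subject_index(b))
}

# Hit pairs between two interval sets via GenomicRanges; returns a tibble of
# (query row, subject row, overlap bp).
#' @noRd
overlap_pairs <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) {
    return(tibble::tibble(query = integer(), subject = integer(), bp = numeric()))
  }
  # seqlevel mismatch between query and subject is expected (e.g. chr2-only
  # reference); silence the Seqinfo merge note
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(to_gr(a), to_gr(b), ignore.strand = TRUE))
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  bp <- pmin(a$end[q], b$end[s]) - pmax(a$start[q], b$start[s])
  tibble::tibble(query = q, subject = s, bp = bp)
}
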