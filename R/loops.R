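#' Chromatin loops as tibbles
#'
#' A loop is a cis (same-chromosome) interaction between a left and a right
#' anchor. Its span runs from the outer coordinate of the left anchor to the
#' outer coordinate of the right anchor; the span is the unit of overlap
#' scoring and insulation. Anchors are stored in canonical order
#' (`start1 <= start2`).
#'
#' @param chrom Chromosome (both anchors; loops are cis only).
#' @param start1,end1 Left anchor, 0-based half-open.
#' @param start2,end2 Right anchor.
#' @param qvalue Optional interaction q-value in `[0, 1]` (`NA` if absent).
#' @param label One of `"none"`, `"overinteracting"`, `"underinteracting"` —
#'   the differential-loop call carried by H3K27ac loop sets.
#' @return A tibble with columns `chrom, start1, end1, start2, end2, qvalue,
#'   label` and a `loop_id` row identifier.
#' @examples
#' gloops("chr1", 100e3, 105e3, 200e3, 205e3)
#' @export
gloops <- function(chrom, start1, end1, start2, end2,
                   qvalue = NA_real_, label = "none") {
  out <- tibble::tibble(chrom = as.character(chrom),
                        start1 = as.numeric(start1), end1 = as.numeric(end1),
                        start2 = as.numeric(start2), end2 = as.numeric(end2),
                        qvalue = as.numeric(qvalue),
                        label = as.character(label))
  # canonical order: left anchor first
  swap <- out$start1 > out$start2
  if (any(swap)) {
    tmp <- out[swap, c("start1", "end1")]
    out[swap, c("start1", "end1")] <- out[swap, c("start2", "end2")]
    out[swap, c("start2", "end2")] <- tmp
  }
  bad <- which(!(out$start1 >= 0 & out$start1 < out$end1 &
                   out$start2 >= 0 & out$start2 < out$end2))
  if (length(bad)) stop("invalid anchor coordinates at row(s): ",
                        paste(utils::head(bad, 5), collapse = ", "))
  bad_lab <- !out$label %in% c("none", "overinteracting", "underinteracting")
  if (any(bad_lab)) stop("invalid loop label(s): ",
                         paste(unique(out$label[bad_lab]), collapse = ", "))
  out$loop_id <- seq_len(nrow(out))
  out
}

#' Loop spans (outer anchor coordinates)
#'
#' @param loops A loop tibble ([gloops()]).
#' @return Interval tibble with one span per loop and its `loop_id`.
#' @export
loop_spans <- function(loops) {
  tibble::tibble(chrom = loops$chrom, start = loops$start1, end = loops$end2,
                 strand = "*", loop_id = loops$loop_id)
}

#' Loop anchors as intervals
#'
#' @param loops A loop tibble.
#' @return Interval tibble with both anchors of every loop (`side` column),
#'   keyed by `loop_id`.
#' @export
loop_anchors <- function(loops) {
  tibble::tibble(
    chrom = rep(loops$chrom, 2),
    start = c(loops$start1, loops$start2),
    end = c(loops$end1, loops$end2),
    strand = "*",
    loop_id = rep(loops$loop_id, 2),
    side = rep(c("left", "right"), each = nrow(loops)))
}

#' Randomly relocate loops as rigid units
#'
#' Each loop moves as a rigid span: anchor lengths and the gap between anchors
#' are conserved, so only the span's position (and possibly chromosome)
#' changes. Placement follows the same capacity-weighted rule as
#' [shuffle_intervals()]. Loops remain cis by construction.
#'
#' @inheritParams shuffle_intervals
#' @param loops Loop tibble.
#' @return Loop tibble with conserved anchor/gap geometry.
#' @export
shuffle_loops <- function(loops, genome, seed, same_chrom = FALSE) {
  if (nrow(loops) == 0) return(loops)
  withr::with_seed(seed, shuffle_loops_impl(loops, genome, same_chrom))
}

#' @noRd
shuffle_loops_impl <- function(loops, genome, same_chrom = FALSE) {
  spans <- tibble::tibble(chrom = loops$chrom, start = loops$start1,
                          end = loops$end2)
  new_spans <- shuffle_intervals_impl(spans, genome, same_chrom)
  shift <- new_spans$start - loops$start1
  out <- loops
  out$chrom <- new_spans$chrom
  out$start1 <- loops$start1 + shift
  out$end1 <- loops$end1 + shift
  out$start2 <- loops$start2 + shift
  out$end2 <- loops$end2 + shift
  out
}
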