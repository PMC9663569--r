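#' Chromosome-size table
#'
#' A genome, for this package, is just a registry of chromosome names and
#' lengths (the UCSC "chrom.sizes" dialect). It bounds every coordinate and
#' drives the randomised interval/loop shuffling.
#'
#' @param x A named numeric vector (names = chromosomes, values = lengths in
#'   bp), or a data frame whose first two columns are chromosome and length.
#' @return A tibble with columns `chrom` (character) and `size` (numeric bp).
#' @examples
#' as_genome(c(chr1 = 1e6, chr2 = 5e5))
#' @export
as_genome <- function(x) {
  if (is.data.frame(x)) {
    out <- tibble::tibble(chrom = as.character(x[[1]]), size = as.numeric(x[[2]]))
  } else if (is.numeric(x) && !is.null(names(x))) {
    out <- tibble::tibble(chrom = names(x), size = as.numeric(x))
  } else {
    stop("`x` must be a named numeric vector or a two-column data frame")
  }
  if (anyDuplicated(out$chrom)) stop("duplicated chromosome names in genome")
  if (any(!is.finite(out$size) | out$size <= 0)) {
    stop("chromosome lengths must be positive and finite")
  }
  out
}

#' Read a UCSC-style chrom.sizes file
#'
#' @param path Path to a two-column tab-separated file (chromosome, length).
#' @return A genome tibble (see [as_genome()]).
#' @export
read_chrom_sizes <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("chrom", "size"),
                           colClasses = c("character", "numeric"))
  as_genome(tibble::as_tibble(raw))
}

#' @noRd
genome_size_of <- function(genome, chrom) {
  idx <- match(chrom, genome$chrom)
  if (anyNA(idx)) {
    stop("chromosome(s) not in genome: ",
         paste(unique(chrom[is.na(idx)]), collapse = ", "))
  }
  genome$size[idx]
}
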