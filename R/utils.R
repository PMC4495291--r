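#' @keywords internal
"_PACKAGE"

#' @importFrom stats setNames rexp runif
#' @importFrom utils read.delim write.table head tail
NULL

# Internal coordinate convention: 0-based, half-open [start, end).
# All GTF/GFF3 (1-based inclusive) and BED (0-based half-open) I/O converts
# at the boundary.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a genomic interval
#'
#' Intervals are 0-based half-open, the package-internal convention.
#'
#' @param contig Contig (chromosome/scaffold) name, non-empty string.
#' @param start 0-based inclusive start.
#' @param end Exclusive end; must satisfy `start < end`.
#' @param strand `"+"` or `"-"`.
#' @return A list of class `genomic_interval`.
#' @export
genomic_interval <- function(contig, start, end, strand = "+") {
  stopifnot(is.character(contig), length(contig) == 1L, nzchar(contig))
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 0L || start >= end)
    stop("invalid interval [", start, ", ", end, ") on ", contig)
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  structure(list(contig = contig, start = start, end = end, strand = strand),
            class = "genomic_interval")
}

#' @export
print.genomic_interval <- function(x, ...) {
  cat(sprintf("%s:[%d,%d)%s\n", x$contig, x$start, x$end, x$strand))
  invisible(x)
}

interval_width <- function(x) x$end - x$start

# half-open overlap on plain numeric vectors (vectorised)
ranges_overlap <- function(s1, e1, s2, e2) s1 < e2 & s2 < e1

# deterministic seed derivation: one named stream per generator stage,
# kept below 2^31 so it is always a valid R integer seed
derive_seed <- function(seed, stream) {
  offsets <- c(isoforms = 11L, genome = 23L, codons = 37L, jitter = 53L,
               screen = 67L, null = 71L, acceptance = 83L)
  off <- offsets[[stream]] %||% 97L
  as.integer((as.numeric(seed) * 2654435761 + off * 97) %% 2147483647)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}
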