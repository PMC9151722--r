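#' @keywords internal
"_PACKAGE"

# Base alphabet used throughout; row order of the pileup tensor's base axis is
# A,C,G,T on the forward strand followed by A,C,G,T on the reverse strand.
DNA_BASES <- c("A", "C", "G", "T")

# Allele symbols for the 21-class genotype head, in canonical order.
GT_SYMBOLS <- c("A", "C", "G", "T", "Ins", "Del")

base_index <- function(b) match(b, DNA_BASES)

#' Round half away from zero at a fixed number of decimals
#'
#' Report-level rounding used when printing metrics: 0.90205 at 4 decimals
#' becomes 0.9021 (base R's `round` would give 0.902 under banker's rounding).
#'
#' @param x numeric vector
#' @param digits number of decimals
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 4) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Deterministic child seeds derived from a user seed; kept below 2^31.
derive_seed <- function(seed, stream) {
  (as.integer(seed) %% 1000000L) * 2003L + as.integer(stream) %% 2003L
}

#' Genomic region (0-based, half-open)
#'
#' Coordinate carrier used by the scanning and calling entry points. Internally
#' every coordinate in depthlift is 0-based half-open; VCF output is 1-based.
#'
#' @param contig contig name
#' @param start 0-based inclusive start
#' @param end 0-based exclusive end
#' @return an object of class `genome_region`
#' @export
genome_region <- function(contig, start, end) {
  stopifnot(is.character(contig), length(contig) == 1L,
            start >= 0, start < end)
  structure(list(contig = contig, start = as.integer(start),
                 end = as.integer(end)),
            class = "genome_region")
}

#' @export
print.genome_region <- function(x, ...) {
  cat(sprintf("<region %s:%d-%d (0-based half-open)>\n", x$contig, x$start,
              x$end))
  invisible(x)
}

log_msg <- function(...) {
  message(sprintf("[depthlift %s] ", format(Sys.time(), "%H:%M:%S")),
          sprintf(...))
}
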