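# Classification targets for the multi-task caller. All label indices are
# 0-based, matching the head layouts:
#   gt21     0..20  unordered allele-symbol pair over {A,C,G,T,Ins,Del}
#   zygosity 0..2   hom-ref, het, hom-alt
#   len1/len2 0..32 allele length change in [-16, +16] mapped to delta + 16
# They are converted to 1-based positions only when indexing R vectors.

LEN_CLASSES <- 33L
ZERO_LEN_INDEX <- 16L   # length change 0

#' The 21 genotype classes
#'
#' All unordered pairs with repetition over the six allele symbols
#' A, C, G, T, Ins, Del in canonical lexicographic order (A < C < G < T <
#' Ins < Del). The row number minus one is the gt21 class index.
#'
#' @return data.frame with character columns `a1`, `a2` (a1 <= a2 in symbol
#'   order), 21 rows
#' @export
genotype_class_table <- function() {
  n <- length(GT_SYMBOLS)
  a1 <- character(0); a2 <- character(0)
  for (i in seq_len(n)) for (j in i:n) {
    a1 <- c(a1, GT_SYMBOLS[i]); a2 <- c(a2, GT_SYMBOLS[j])
  }
  data.frame(a1 = a1, a2 = a2, stringsAsFactors = FALSE)
}

# gt21 index (0-based) of an unordered symbol pair.
gt21_index <- function(s1, s2) {
  tab <- genotype_class_table()
  o <- order(match(c(s1, s2), GT_SYMBOLS))
  p <- c(s1, s2)[o]
  idx <- which(tab$a1 == p[1] & tab$a2 == p[2])
  stopifnot(length(idx) == 1L)
  idx - 1L
}

# Symbol of one allele relative to the site's (normalized) REF.
allele_symbol <- function(ref, allele) {
  if (nchar(allele) == nchar(ref)) {
    substr(allele, 1L, 1L)     # SNP or the reference allele itself
  } else if (nchar(allele) > nchar(ref)) "Ins" else "Del"
}

len_index <- function(delta, flank = 16L) {
  as.integer(max(-flank, min(flank, delta)) + ZERO_LEN_INDEX)
}

#' Label a candidate site from a truth record
#'
#' With no truth record the site is labeled homozygous-reference: zygosity 0,
#' gt21 = the homozygous pair of the reference base, both length indices at
#' zero change. With a truth record, the two genotype alleles are mapped to
#' symbols (base for SNPs/ref allele, Ins/Del for length changes) and length
#' deltas `nchar(alt) - nchar(ref)` clipped to +/- `flank`.
#'
#' @param site one-row candidate data.frame (needs `ref_base`)
#' @param truth_record NULL, or list(pos, ref, alt = character vector,
#'   gt = integer vector of two allele indices, 0 = ref) as from [read_vcf()]
#' @param flank window half-width used for length clipping
#' @return list(gt21, zygosity, len1, len2), all 0-based indices
#' @export
label_site <- function(site, truth_record = NULL, flank = 16L) {
  if (is.null(truth_record)) {
    return(list(gt21 = gt21_index(site$ref_base, site$ref_base),
                zygosity = 0L, len1 = ZERO_LEN_INDEX, len2 = ZERO_LEN_INDEX))
  }
  alleles <- c(truth_record$ref, truth_record$alt)
  if (!all(grepl("^[ACGT]+$", alleles))) {
    warning("truth record at pos ", truth_record$pos,
            " has non-ACGT alleles; labeled hom-ref")
    return(label_site(site, NULL, flank))
  }
  gt <- truth_record$gt
  stopifnot(length(gt) == 2L, all(gt >= 0L), all(gt <= length(truth_record$alt)))
  a <- alleles[gt + 1L]
  sym <- vapply(a, allele_symbol, character(1), ref = truth_record$ref,
                USE.NAMES = FALSE)
  delta <- nchar(a) - nchar(truth_record$ref)
  zyg <- if (all(gt == 0L)) 0L else if (any(gt == 0L) || gt[1] != gt[2]) 1L
         else 2L
  # order the pair (and its deltas) canonically by symbol
  o <- order(match(sym, GT_SYMBOLS), delta)
  list(gt21 = gt21_index(sym[1], sym[2]),
       zygosity = zyg,
       len1 = len_index(delta[o[1]], flank),
       len2 = len_index(delta[o[2]], flank))
}
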