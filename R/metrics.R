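# Genotype-aware benchmarking of a call set against a truth set. This is a
# deliberate simplification of haplotype-aware comparators (rtg vcfeval): a
# call is a true positive iff a truth record matches it on contig, position,
# REF, ALT set and unordered genotype after left-normalization.

#' Match called against truth variants
#'
#' @param called data.frame of calls (as from [read_vcf()] or [call_region()])
#' @param truth data.frame of truth records (as from [read_vcf()])
#' @param regions optional data.frame with columns contig, start, end
#'   (0-based half-open, BED semantics); records outside are ignored
#' @return list(tp, fp, fn) confusion counts
#' @export
match_calls <- function(called, truth, regions = NULL) {
  if (!is.null(regions)) {
    called <- filter_regions(called, regions)
    truth <- filter_regions(truth, regions)
  }
  ckey <- record_keys(called)
  tkey <- record_keys(truth)
  if (anyDuplicated(ckey)) {
    warning("duplicate call records; keeping first occurrence")
    called <- called[!duplicated(ckey), , drop = FALSE]
    ckey <- ckey[!duplicated(ckey)]
  }
  if (anyDuplicated(tkey)) {
    warning("duplicate truth records; keeping first occurrence")
    truth <- truth[!duplicated(tkey), , drop = FALSE]
    tkey <- tkey[!duplicated(tkey)]
  }
  tp <- sum(ckey %in% tkey)
  list(tp = tp, fp = length(ckey) - tp, fn = length(tkey) - tp)
}

record_keys <- function(df) {
  if (!nrow(df)) return(character(0))
  vapply(seq_len(nrow(df)), function(i)
    variant_key(df$contig[i], df$pos[i], df$ref[i], df$alt[i], df$gt[i]),
    character(1))
}

filter_regions <- function(df, regions) {
  if (!nrow(df)) return(df)
  keep <- vapply(seq_len(nrow(df)), function(i)
    any(regions$contig == df$contig[i] & df$pos[i] >= regions$start &
          df$pos[i] < regions$end), logical(1))
  df[keep, , drop = FALSE]
}

#' Precision, recall and F1 from confusion counts
#'
#' precision = tp/(tp+fp), recall = tp/(tp+fn),
#' F1 = 2*P*R/(P+R); a zero denominator yields 0 and sets `degenerate`.
#'
#' @param counts list or data.frame with tp, fp, fn
#' @return list(precision, recall, f1, degenerate)
#' @export
compute_metrics <- function(counts) {
  tp <- as.numeric(counts$tp); fp <- as.numeric(counts$fp)
  fn <- as.numeric(counts$fn)
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  degenerate <- FALSE
  precision <- if (tp + fp > 0) tp / (tp + fp) else { degenerate <- TRUE; 0 }
  recall <- if (tp + fn > 0) tp / (tp + fn) else { degenerate <- TRUE; 0 }
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall)
  else { degenerate <- TRUE; 0 }
  list(precision = precision, recall = recall, f1 = f1,
       degenerate = degenerate)
}

#' F1 score from precision and recall
#'
#' @param precision,recall fractions in [0, 1]
#' @return harmonic mean (0 when both are 0)
#' @export
f1_score <- function(precision, recall) {
  if (precision + recall == 0) return(0)
  2 * precision * recall / (precision + recall)
}

#' Read a BED file (0-based half-open)
#'
#' @param path BED path
#' @return data.frame with contig, start, end
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  stats::setNames(df[, 1:3], c("contig", "start", "end"))
}
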