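# Paired low/high-depth training examples.

#' Build paired low/high-depth training examples over a region
#'
#' The candidate set is the union of the low-depth candidate scan and the
#' truth variant positions in the region; each site yields the low-depth
#' image, the high-depth image at the same site, and the truth label
#' (hom-ref when no truth record exists). Output is position-sorted and
#' deterministic.
#'
#' @param low_aln,high_aln `read_set`s of the down-sampled and full-depth
#'   alignments
#' @param truth truth variants (data.frame from [read_vcf()], or NULL)
#' @param region a `genome_region`
#' @param ref a `reference`
#' @param min_af,min_depth candidate screen applied to the low alignment
#' @param flank window half-width
#' @return list of examples: list(site, low_image, high_image, label)
#' @export
make_training_pairs <- function(low_aln, high_aln, truth, region, ref,
                                min_af = 0.2, min_depth = 4, flank = 16L) {
  sites <- scan_candidates(low_aln, region, ref, min_af, min_depth)
  tpos <- integer(0)
  if (!is.null(truth) && nrow(truth)) {
    sel <- truth$contig == region$contig & truth$pos >= region$start &
      truth$pos < region$end
    tpos <- truth$pos[sel]
  }
  allpos <- sort(unique(c(sites$pos, tpos)))
  pc_low <- pileup_counts(low_aln, ref, region$contig)
  out <- vector("list", length(allpos))
  for (i in seq_along(allpos)) {
    p <- allpos[i]
    site <- candidate_site(region$contig, p, ref_base_at(ref, region$contig,
                                                         p),
                           depth = pc_low$depth[p + 1L])
    low_img <- window_image(low_aln, ref, region$contig, p, flank)
    high_img <- window_image(high_aln, ref, region$contig, p, flank)
    if (all(high_img == 0))
      log_msg("truth site %s:%d has no high-depth coverage", region$contig,
              p)
    rec <- truth_at(truth, region$contig, p)
    out[[i]] <- list(site = site, low_image = low_img,
                     high_image = high_img,
                     label = label_site(site, rec, flank))
  }
  out
}

#' Save / load a training dataset archive
#'
#' A single-file array archive with a JSON sidecar recording the flank,
#' channel order and site list.
#'
#' @param dataset list of training examples
#' @param path destination path (.rds)
#' @param flank window half-width recorded in the sidecar
#' @return `path`, invisibly
#' @export
save_dataset <- function(dataset, path, flank = 16L) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  saveRDS(dataset, path)
  sites <- lapply(dataset, function(e)
    list(contig = e$site$contig, pos = e$site$pos))
  meta <- list(n = length(dataset), flank = flank,
               channel_order = c("ref_match", "insertion", "deletion",
                                 "snv_alt"),
               base_rows = c("A", "C", "G", "T", "A-", "C-", "G-", "T-"),
               sites = sites)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_dataset
#' @export
load_dataset <- function(path) readRDS(path)

# Label-class tally used by the make-dataset command report.
dataset_label_summary <- function(dataset) {
  zyg <- vapply(dataset, function(e) e$label$zygosity, integer(1))
  table(factor(zyg, levels = 0:2,
               labels = c("hom_ref", "het", "hom_alt")))
}
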