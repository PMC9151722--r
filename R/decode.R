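# Decoding caller head probabilities into concrete variant calls.
#
# The decoding rule set (the upstream caller describes its post-processing
# only by reference) is: zygosity argmax gates everything; hom-ref sites emit
# nothing; otherwise the highest-probability gt21 class *consistent* with the
# zygosity is chosen (het classes contain the reference symbol or are a pair
# of two distinct non-reference symbols, giving a 1/2 multi-allelic call;
# hom-alt classes are homozygous pairs of a non-reference symbol). SNP
# alleles come from the class symbols; insertion/deletion sequences are
# reconstructed as the most frequent inserted/deleted sequence among
# supporting reads, with length guided by the decoded length heads.
# QUAL is -10*log10(1 - min(max p_zyg, max p_gt21)), capped at 60.

#' Decode one site's attribute probabilities into a variant call
#'
#' @param probs list(gt21 (21), zygosity (3), len1 (33), len2 (33)) of
#'   probability vectors
#' @param site one-row candidate data.frame (contig, pos, ref_base)
#' @param aln optional `read_set` used to reconstruct indel allele sequences
#' @param ref a `reference` (needed for deletion alleles)
#' @param flank window half-width (clips decodable indel length)
#' @return NULL (hom-ref) or a one-row data.frame: contig, pos, ref, alt,
#'   gt, qual, filter
#' @export
decode_site <- function(probs, site, aln = NULL, ref = NULL, flank = 16L) {
  zyg <- which.max(probs$zygosity) - 1L
  if (zyg == 0L) return(NULL)
  tab <- genotype_class_table()
  rb <- site$ref_base
  if (!rb %in% DNA_BASES) return(NULL)
  het <- zyg == 1L
  if (het) {
    consistent <- (tab$a1 == rb | tab$a2 == rb) & tab$a1 != tab$a2
    multi <- tab$a1 != rb & tab$a2 != rb & tab$a1 != tab$a2
    consistent <- consistent | multi
  } else {
    consistent <- tab$a1 == tab$a2 & tab$a1 != rb
  }
  cand <- which(consistent)
  k <- cand[which.max(probs$gt21[cand])]
  syms <- c(tab$a1[k], tab$a2[k])
  qual <- min(60, -10 * log10(max(1e-6,
    1 - min(max(probs$zygosity), max(probs$gt21)))))
  deltas <- sort(c(which.max(probs$len1), which.max(probs$len2)) - 1L -
                   ZERO_LEN_INDEX)
  filter <- "PASS"

  alt_syms <- if (het && all(syms != rb)) syms else setdiff(syms, rb)
  if (!length(alt_syms)) return(NULL)   # degenerate ref/ref class
  alts <- character(0)
  for (i in seq_along(alt_syms)) {
    s <- alt_syms[i]
    # pick the decoded length for this allele: insertions take the largest
    # positive delta, deletions the most negative; fall back to 1
    if (s == "Ins") {
      want <- max(deltas, 1L)
      if (want > flank) { want <- flank; filter <- "lowqual" }
      ins_seq <- consensus_indel(aln, ref, site, +want)
      alts <- c(alts, paste0(rb, ins_seq))
    } else if (s == "Del") {
      want <- -min(deltas, -1L)
      if (want > flank) { want <- flank; filter <- "lowqual" }
      alts <- c(alts, del_alt(ref, site, want))
    } else {
      alts <- c(alts, s)
    }
  }
  ref_allele <- rb
  # deletions lengthen the REF allele: use the longest implied ref span
  if (any(alt_syms == "Del")) {
    dl <- -min(deltas, -1L)
    dl <- min(dl, flank)
    L <- contig_length(ref, site$contig)
    dl <- min(dl, L - site$pos - 1L)
    ref_allele <- paste(ref_chars(ref, site$contig, site$pos,
                                  min(L, site$pos + dl + 1L)), collapse = "")
    # non-deletion alt alleles must carry the same trailing context
    alts <- vapply(seq_along(alt_syms), function(i) {
      if (alt_syms[i] == "Del") substr(ref_allele, 1L, 1L)
      else paste0(alts[i], substring(ref_allele, 2L))
    }, character(1))
  }
  alts[alts == ref_allele] <- paste0(ref_allele, "N")  # guard: ALT != REF
  alts <- unique(alts)
  gt <- if (!het) "1/1" else if (length(alts) == 2L) "1/2" else "0/1"
  data.frame(contig = site$contig, pos = site$pos, ref = ref_allele,
             alt = paste(alts, collapse = ","), gt = gt,
             qual = qual, filter = filter, stringsAsFactors = FALSE)
}

# Most frequent inserted (delta > 0) sequence of the decoded length among
# reads anchored at the site; "N" padding when no read supports one.
consensus_indel <- function(aln, ref, site, delta) {
  want <- abs(delta)
  if (!is.null(aln)) {
    rd <- aln$reads[aln$reads$contig == site$contig, , drop = FALSE]
    seqs <- character(0)
    for (i in seq_len(nrow(rd))) {
      if (rd$pos[i] > site$pos ||
          rd$pos[i] + cigar_ref_span(rd$cigar[i]) <= site$pos) next
      e <- read_events(rd$pos[i], rd$cigar[i], rd$seq[i])
      sel <- e$i_pos == site$pos
      if (any(sel)) seqs <- c(seqs, paste(e$i_base[sel], collapse = ""))
    }
    if (length(seqs)) {
      pref <- seqs[nchar(seqs) == want]
      pool <- if (length(pref)) pref else seqs
      tt <- sort(table(pool), decreasing = TRUE)
      return(names(tt)[1])
    }
  }
  paste(rep("N", want), collapse = "")
}

del_alt <- function(ref, site, want) site$ref_base

#' Call variants over a region
#'
#' The full inference pipeline: scan candidates, featurize, project with the
#' generator, classify with the caller, decode. With `use_generator = FALSE`
#' the low-depth image is fed to the caller twice (the plain-caller
#' baseline/ablation).
#'
#' @param g_params,c_params trained parameters ([fit()] output)
#' @param aln a `read_set`
#' @param ref a `reference`
#' @param region a `genome_region`
#' @param min_af,min_depth candidate screen (defaults 0.2 / 4)
#' @param flank window half-width
#' @param use_generator project images through G before calling?
#' @param batch_size inference batch size
#' @return data.frame of calls (possibly 0 rows): contig, pos (0-based),
#'   ref, alt, gt, qual, filter; position-sorted
#' @export
call_region <- function(g_params, c_params, aln, ref, region, min_af = 0.2,
                        min_depth = 4, flank = 16L, use_generator = TRUE,
                        batch_size = 512L) {
  sites <- scan_candidates(aln, region, ref, min_af, min_depth)
  empty <- data.frame(contig = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      gt = character(0), qual = numeric(0),
                      filter = character(0), stringsAsFactors = FALSE)
  if (!nrow(sites)) return(empty)
  imgs <- lapply(seq_len(nrow(sites)), function(i)
    window_image(aln, ref, sites$contig[i], sites$pos[i], flank))
  calls <- list()
  for (b0 in seq(1L, nrow(sites), by = batch_size)) {
    ii <- b0:min(b0 + batch_size - 1L, nrow(sites))
    low <- as_batch_matrix(imgs[ii])
    gen <- if (use_generator) generator_forward(g_params, low)$out else low
    pr <- caller_forward(c_params, gen, low)$probs
    for (j in seq_along(ii)) {
      probs <- list(gt21 = pr$gt21[, j], zygosity = pr$zygosity[, j],
                    len1 = pr$len1[, j], len2 = pr$len2[, j])
      cl <- decode_site(probs, sites[ii[j], ], aln, ref, flank)
      if (!is.null(cl)) calls[[length(calls) + 1L]] <- cl
    }
  }
  if (!length(calls)) return(empty)
  out <- do.call(rbind, calls)
  out[order(out$contig, out$pos), , drop = FALSE]
}
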