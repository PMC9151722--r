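# Counting pileup featurization.
#
# The unit the networks consume is a 33 x 8 x 4 tensor of non-negative counts
# around a candidate site: axis 1 = reference positions in [pos-16, pos+16],
# axis 2 = stranded read base (A,C,G,T forward then A-,C-,G-,T- reverse),
# axis 3 = counting channel:
#   1: reference-matching base count      2: insertion base count
#   3: deletion count                     4: single-nucleotide alternative count
# Flattened along the third axis it becomes a 33 x 32 image (column 4*(b-1)+s
# for base row b and channel s, both 1-based here).
#
# Bookkeeping rules (fixed so the count-conservation invariant is testable):
# each aligned read base increments channel 1 if it equals the reference base
# and channel 4 otherwise, on its own base row; each base of an insertion is
# counted on the inserted base's row at the anchor column (the reference
# position left of the insertion); a deletion increments channel 3 on the
# row of the deleted reference base. Read bases of "N" contribute nothing.

N_BASE_ROWS <- 8L
N_CHANNELS <- 4L
IMG_COLS <- N_BASE_ROWS * N_CHANNELS   # 32

# Column index (1-based) in the flattened image for base row b (1..8) and
# channel s (1..4).
img_col <- function(b, s) (b - 1L) * N_CHANNELS + s

# Per-contig pileup summary for a whole alignment:
#   counts    L x 32 matrix in flattened-image column order
#   ins_reads L vector, number of reads with an insertion anchored at p
#   depth     L vector, reads whose alignment covers p (deletions included)
# Cached on the read_set so repeated window extraction is a row slice.
pileup_counts <- function(aln, ref, contig) {
  key <- paste0("pc_", contig)
  if (!is.null(aln$cache[[key]])) return(aln$cache[[key]])
  L <- contig_length(ref, contig)
  rchars <- ref$chars[[contig]]
  rd <- aln$reads[aln$reads$contig == contig, , drop = FALSE]
  ev_pos <- vector("list", nrow(rd) * 3L)
  ev_col <- vector("list", nrow(rd) * 3L)
  ins_anchor <- vector("list", nrow(rd))
  k <- 0L
  for (i in seq_len(nrow(rd))) {
    e <- read_events(rd$pos[i], rd$cigar[i], rd$seq[i])
    srow <- if (rd$strand[i] == "-") 4L else 0L
    if (length(e$m_pos)) {
      b <- base_index(e$m_base)
      ok <- !is.na(b) & e$m_pos >= 0L & e$m_pos < L
      ch <- ifelse(e$m_base[ok] == rchars[e$m_pos[ok] + 1L], 1L, 4L)
      k <- k + 1L
      ev_pos[[k]] <- e$m_pos[ok]
      ev_col[[k]] <- img_col(b[ok] + srow, ch)
    }
    if (length(e$i_pos)) {
      b <- base_index(e$i_base)
      ok <- !is.na(b) & e$i_pos >= 0L & e$i_pos < L
      k <- k + 1L
      ev_pos[[k]] <- e$i_pos[ok]
      ev_col[[k]] <- img_col(b[ok] + srow, 2L)
      ins_anchor[[i]] <- unique(e$i_anchor)
    }
    if (length(e$d_pos)) {
      ok <- e$d_pos >= 0L & e$d_pos < L
      b <- base_index(rchars[e$d_pos[ok] + 1L])
      ok2 <- !is.na(b)
      k <- k + 1L
      ev_pos[[k]] <- e$d_pos[ok][ok2]
      ev_col[[k]] <- img_col(b[ok2] + srow, 3L)
    }
  }
  pos <- unlist(ev_pos[seq_len(k)], use.names = FALSE)
  col <- unlist(ev_col[seq_len(k)], use.names = FALSE)
  counts <- matrix(0, nrow = L, ncol = IMG_COLS)
  if (length(pos)) {
    idx <- pos + 1L + L * (col - 1L)
    tab <- tabulate(idx, nbins = L * IMG_COLS)
    counts[] <- tab
  }
  ins_reads <- tabulate(unlist(ins_anchor, use.names = FALSE) + 1L, nbins = L)
  base_cols <- c(img_col(1:8, 1L), img_col(1:8, 4L), img_col(1:8, 3L))
  depth <- as.integer(round(rowSums(counts[, base_cols, drop = FALSE])))
  out <- list(counts = counts, ins_reads = ins_reads, depth = depth)
  assign(key, out, envir = aln$cache)
  out
}

#' Scan an alignment for candidate variant sites
#'
#' Emits every position in `region` whose read depth is at least `min_depth`
#' and whose alternative-support fraction (mismatching bases, deletions, and
#' reads carrying an insertion anchored at the position) is at least `min_af`
#' (the 0.2 allele-frequency screen applied before featurization).
#'
#' @param aln a `read_set`
#' @param region a `genome_region`
#' @param ref a `reference`
#' @param min_af minimum alternative allele fraction (default 0.2)
#' @param min_depth minimum read depth (default 4)
#' @return data.frame of candidate sites with columns contig, pos (0-based),
#'   ref_base, depth, alt_support, alt_fraction, sorted by position
#' @export
scan_candidates <- function(aln, region, ref, min_af = 0.2, min_depth = 4) {
  L <- contig_length(ref, region$contig)
  stopifnot(region$end <= L)
  pc <- pileup_counts(aln, ref, region$contig)
  p <- (region$start + 1L):region$end   # 1-based rows
  depth <- pc$depth[p]
  alt <- rowSums(pc$counts[p, img_col(1:8, 4L), drop = FALSE]) +
    rowSums(pc$counts[p, img_col(1:8, 3L), drop = FALSE]) +
    pc$ins_reads[p]
  af <- ifelse(depth > 0, pmin(alt / pmax(depth, 1), 1), 0)
  keep <- which(depth >= min_depth & af >= min_af)
  if (!length(keep))
    return(data.frame(contig = character(0), pos = integer(0),
                      ref_base = character(0), depth = integer(0),
                      alt_support = integer(0), alt_fraction = numeric(0),
                      stringsAsFactors = FALSE))
  data.frame(
    contig = region$contig,
    pos = p[keep] - 1L,
    ref_base = ref$chars[[region$contig]][p[keep]],
    depth = depth[keep],
    alt_support = as.integer(round(alt[keep])),
    alt_fraction = af[keep],
    stringsAsFactors = FALSE)
}

candidate_site <- function(contig, pos, ref_base, depth = 0L,
                           alt_support = 0L) {
  data.frame(contig = contig, pos = as.integer(pos), ref_base = ref_base,
             depth = as.integer(depth), alt_support = as.integer(alt_support),
             alt_fraction = ifelse(depth > 0, pmin(alt_support / depth, 1), 0),
             stringsAsFactors = FALSE)
}

#' Build the pileup count tensor at a site
#'
#' @param aln a `read_set`
#' @param site one-row data.frame as produced by [scan_candidates()]
#' @param ref a `reference`
#' @param flank window half-width (default 16, giving 33 positions)
#' @return a `pileup_tensor`: list(site, flank, data = (2*flank+1) x 8 x 4
#'   array). Window positions outside the contig are zero padding.
#' @export
build_pileup_tensor <- function(aln, site, ref, flank = 16) {
  stopifnot(flank >= 1)
  img <- window_image(aln, ref, site$contig, site$pos, flank)
  structure(list(site = site, flank = as.integer(flank),
                 data = unflatten_image(img)),
            class = "pileup_tensor")
}

# Flattened window image directly from the cached per-contig count matrix.
window_image <- function(aln, ref, contig, pos, flank = 16) {
  L <- contig_length(ref, contig)
  pc <- pileup_counts(aln, ref, contig)
  w <- 2L * flank + 1L
  img <- matrix(0, nrow = w, ncol = IMG_COLS)
  lo <- pos - flank; hi <- pos + flank
  rlo <- max(lo, 0L); rhi <- min(hi, L - 1L)
  if (rlo <= rhi)
    img[(rlo - lo + 1L):(rhi - lo + 1L), ] <-
      pc$counts[(rlo + 1L):(rhi + 1L), , drop = FALSE]
  attr(img, "provenance") <- "observed"
  img
}

#' Flatten a pileup tensor to a 2D image
#'
#' Column index is 4*(b-1)+s for base row b and channel s (1-based); the
#' operation is lossless and inverted exactly by [unflatten_image()].
#'
#' @param t a `pileup_tensor` or a bare (w x 8 x 4) array
#' @param provenance provenance tag for the image
#' @return a w x 32 matrix with a `provenance` attribute
#' @export
flatten_tensor <- function(t, provenance = "observed") {
  a <- if (inherits(t, "pileup_tensor")) t$data else t
  stopifnot(length(dim(a)) == 3L, dim(a)[2] == N_BASE_ROWS,
            dim(a)[3] == N_CHANNELS)
  img <- aperm(a, c(1, 3, 2))
  dim(img) <- c(dim(a)[1], IMG_COLS)
  attr(img, "provenance") <- provenance
  img
}

#' Inverse of [flatten_tensor()]
#'
#' @param img a w x 32 matrix
#' @return a w x 8 x 4 array
#' @export
unflatten_image <- function(img) {
  stopifnot(ncol(img) == IMG_COLS)
  a <- img
  attributes(a) <- NULL
  dim(a) <- c(nrow(img), N_CHANNELS, N_BASE_ROWS)
  aperm(a, c(1, 3, 2))
}
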