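# Aligned reads. A `read_set` is a data.frame with one row per read:
#   qname  read name
#   contig reference name
#   pos    0-based leftmost aligned reference position
#   strand "+" or "-" (SEQ is stored in reference orientation, as in BAM)
#   cigar  CIGAR string (M/I/D/S ops; =/X accepted on input)
#   seq    read sequence in reference orientation
# An attached environment caches per-contig pileup count matrices so that
# repeated featurization over one alignment is cheap.

#' Construct a read set
#'
#' @param df data.frame with columns qname, contig, pos, strand, cigar, seq
#' @return an object of class `read_set`
#' @export
read_set <- function(df) {
  need <- c("qname", "contig", "pos", "strand", "cigar", "seq")
  stopifnot(all(need %in% names(df)))
  df <- df[order(df$contig, df$pos), need, drop = FALSE]
  rownames(df) <- NULL
  df$pos <- as.integer(df$pos)
  structure(list(reads = df, cache = new.env(parent = emptyenv())),
            class = "read_set")
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("<read_set: %d reads over %s>\n", nrow(x$reads),
              paste(unique(x$reads$contig), collapse = ",")))
  invisible(x)
}

n_reads <- function(aln) nrow(aln$reads)

CIGAR_RE <- "([0-9]+)([MIDNSHP=X])"

parse_cigar <- function(cigar) {
  m <- gregexpr(CIGAR_RE, cigar)[[1]]
  parts <- regmatches(cigar, list(m))[[1]]
  lens <- as.integer(sub("[MIDNSHP=X]$", "", parts))
  ops <- sub("^[0-9]+", "", parts)
  list(ops = ops, lens = lens)
}

# Reference span [pos, end) consumed by a CIGAR.
cigar_ref_span <- function(cigar) {
  cg <- parse_cigar(cigar)
  sum(cg$lens[cg$ops %in% c("M", "D", "N", "=", "X")])
}

# Expand one read into per-position alignment events.
# Returns a list of integer/character vectors:
#   m_pos/m_base : aligned (non-deleted) read bases and their ref positions
#   d_pos        : deleted reference positions
#   i_pos/i_base : inserted bases, all attributed to the anchor position
#                  (the reference base immediately left of the insertion)
#   i_anchor     : one entry per insertion event (for read-level alt support)
read_events <- function(pos0, cigar, seq) {
  cg <- parse_cigar(cigar)
  rp <- pos0                      # next reference position (0-based)
  qp <- 1L                        # next query position (1-based)
  qchars <- strsplit(seq, "", fixed = TRUE)[[1]]
  m_pos <- integer(0); m_base <- character(0)
  d_pos <- integer(0)
  i_pos <- integer(0); i_base <- character(0); i_anchor <- integer(0)
  for (k in seq_along(cg$ops)) {
    op <- cg$ops[k]; len <- cg$lens[k]
    if (op %in% c("M", "=", "X")) {
      m_pos <- c(m_pos, rp:(rp + len - 1L))
      m_base <- c(m_base, qchars[qp:(qp + len - 1L)])
      rp <- rp + len; qp <- qp + len
    } else if (op == "I") {
      anchor <- rp - 1L
      if (anchor >= 0L) {         # insertion before the first base: dropped
        i_pos <- c(i_pos, rep.int(anchor, len))
        i_base <- c(i_base, qchars[qp:(qp + len - 1L)])
        i_anchor <- c(i_anchor, anchor)
      }
      qp <- qp + len
    } else if (op %in% c("D", "N")) {
      d_pos <- c(d_pos, rp:(rp + len - 1L))
      rp <- rp + len
    } else if (op == "S") {
      qp <- qp + len
    }                             # H/P consume nothing
  }
  list(m_pos = m_pos, m_base = m_base, d_pos = d_pos,
       i_pos = i_pos, i_base = i_base, i_anchor = i_anchor)
}

#' Write a read set to BAM (sorted + indexed)
#'
#' @param aln a `read_set`
#' @param ref the `reference` the reads are aligned to (for SQ headers)
#' @param path output path; ".bam" appended if missing
#' @return path of the BAM file
#' @export
write_bam <- function(aln, ref, path) {
  path <- sub("\\.bam$", "", path)
  sam <- paste0(path, ".sam")
  rd <- aln$reads
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(ref$lengths), ref$lengths))
  body <- sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t*",
                  rd$qname, ifelse(rd$strand == "-", 16L, 0L), rd$contig,
                  rd$pos + 1L, rd$cigar, rd$seq)
  writeLines(c(hdr, body), sam)
  out <- Rsamtools::asBam(sam, destination = path, overwrite = TRUE,
                          indexDestination = TRUE)
  unlink(sam)
  out
}

#' Load a BAM file as a read set
#'
#' @param path BAM path (index alongside)
#' @param region optional `genome_region`; reads overlapping it are kept
#' @return a `read_set`
#' @export
read_bam <- function(path, region = NULL) {
  what <- c("qname", "flag", "rname", "pos", "cigar", "seq")
  param <- Rsamtools::ScanBamParam(what = what)
  res <- Rsamtools::scanBam(path, param = param)[[1]]
  keep <- !is.na(res$pos)
  df <- data.frame(
    qname = res$qname[keep],
    contig = as.character(res$rname)[keep],
    pos = res$pos[keep] - 1L,
    strand = ifelse(bitwAnd(res$flag[keep], 16L) > 0L, "-", "+"),
    cigar = res$cigar[keep],
    seq = as.character(res$seq)[keep],
    stringsAsFactors = FALSE)
  if (!is.null(region)) {
    span <- vapply(df$cigar, cigar_ref_span, integer(1), USE.NAMES = FALSE)
    df <- df[df$contig == region$contig & df$pos < region$end &
               df$pos + span > region$start, , drop = FALSE]
  }
  read_set(df)
}

#' Down-sample a read set by binomial thinning
#'
#' Each read is kept independently with probability `rate`; this is the
#' read-level protocol behind "0.5ds"/"0.3ds" depth reduction. Deterministic
#' for a fixed seed; read order is preserved.
#'
#' @param aln a `read_set`
#' @param rate keep probability in (0, 1]
#' @param seed integer seed
#' @return a thinned `read_set`
#' @export
downsample <- function(aln, rate, seed) {
  stopifnot(rate > 0, rate <= 1)
  if (rate == 1) return(read_set(aln$reads))
  rng <- local({ set.seed(derive_seed(seed, 7L)); stats::runif(n_reads(aln)) })
  read_set(aln$reads[rng < rate, , drop = FALSE])
}
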