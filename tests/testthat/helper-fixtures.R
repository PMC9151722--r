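# Shared fixtures: tiny hand-built read stacks, small simulations, and an
# independent brute-force pileup counter used as the featurization oracle.

toy_reference <- function(seq, contig = "chrT") {
  reference_from_seqs(stats::setNames(seq, contig))
}

toy_reads <- function(pos, cigar, seq, strand = "+", contig = "chrT") {
  n <- length(pos)
  read_set(data.frame(
    qname = sprintf("t%03d", seq_len(n)),
    contig = contig,
    pos = as.integer(pos),
    strand = rep_len(strand, n),
    cigar = rep_len(cigar, n)[seq_len(n)],
    seq = rep_len(seq, n)[seq_len(n)],
    stringsAsFactors = FALSE))
}

# Independent oracle: walks each read's CIGAR step by step with scalar
# string operations (a different code path from the vectorized counter)
# and tallies the window tensor directly.
brute_force_tensor <- function(aln, ref, contig, pos, flank = 16) {
  w <- 2 * flank + 1
  out <- array(0, c(w, 8, 4))
  rchars <- strsplit(ref$seqs[[contig]], "")[[1]]
  L <- length(rchars)
  rows <- aln$reads[aln$reads$contig == contig, , drop = FALSE]
  for (i in seq_len(nrow(rows))) {
    srow <- if (rows$strand[i] == "-") 4 else 0
    qseq <- strsplit(rows$seq[i], "")[[1]]
    ops <- regmatches(rows$cigar[i],
                      gregexpr("[0-9]+[MIDNSHP=X]", rows$cigar[i]))[[1]]
    rp <- rows$pos[i]; qp <- 1
    add <- function(p, base, ch) {
      col <- p - (pos - flank) + 1
      b <- match(base, c("A", "C", "G", "T"))
      if (col >= 1 && col <= w && !is.na(b) && p >= 0 && p < L)
        out[col, b + srow, ch] <<- out[col, b + srow, ch] + 1
    }
    for (op in ops) {
      len <- as.integer(sub("[A-Z=]", "", op))
      type <- sub("[0-9]+", "", op)
      if (type %in% c("M", "=", "X")) {
        for (j in seq_len(len)) {
          if (rp >= 0 && rp < L) {
            if (qseq[qp] == rchars[rp + 1]) add(rp, qseq[qp], 1)
            else add(rp, qseq[qp], 4)
          }
          rp <- rp + 1; qp <- qp + 1
        }
      } else if (type == "I") {
        for (j in seq_len(len)) {
          if (rp - 1 >= 0) add(rp - 1, qseq[qp], 2)
          qp <- qp + 1
        }
      } else if (type %in% c("D", "N")) {
        for (j in seq_len(len)) {
          if (rp >= 0 && rp < L) add(rp, rchars[rp + 1], 3)
          rp <- rp + 1
        }
      } else if (type == "S") {
        qp <- qp + len
      }
    }
  }
  out
}

# A small noisy diploid simulation shared by several test files (cheap).
small_sim <- function(seed = 7, genome_length = 6000, depth = 20, ...) {
  cfg <- sim_config(genome_length = genome_length, depth = depth,
                    seed = seed, ...)
  genome <- simulate_genome(cfg)
  aln <- simulate_reads(genome, cfg)
  list(cfg = cfg, genome = genome, aln = aln)
}

random_tensor <- function(seed) {
  set.seed(seed)
  array(rpois(33 * 8 * 4, 1), c(33, 8, 4))
}

# Labels as truth-record lists for label_site()
rec <- function(pos, ref, alt, gt) list(pos = pos, ref = ref, alt = alt,
                                        gt = gt)

candidate_site_df <- function(contig, pos, ref_base) {
  data.frame(contig = contig, pos = as.integer(pos), ref_base = ref_base,
             depth = 10L, alt_support = 5L, alt_fraction = 0.5,
             stringsAsFactors = FALSE)
}
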