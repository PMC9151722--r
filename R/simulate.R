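# Diploid genome and long-read simulator.
#
# The generator emulates the data regime the caller is built for: a diploid
# genome with planted SNPs and short indels, ONT-like noisy reads (default
# 5% mismatch / 3% insertion / 3% deletion, ~11% total, inside the "up to
# 15%" third-generation error band) of ~2 kb, emitted pre-aligned at their
# true placement, and seeded binomial read thinning for the down-sampling
# protocol. Everything is reproducible from `seed`.

#' Simulator configuration
#'
#' @param genome_length contig length in bp
#' @param contig_name contig name
#' @param snp_rate per-bp probability of planting a SNP
#' @param indel_rate per-bp probability of planting an indel
#' @param max_indel maximum indel length (must stay within the flank, <= 16)
#' @param het_fraction probability a planted variant is heterozygous
#' @param error_mismatch,error_insertion,error_deletion per-bp read error rates
#' @param read_length_mean mean read length in bp (geometric-tailed)
#' @param depth target mean fold-coverage
#' @param seed integer seed
#' @return a `sim_config` list
#' @export
sim_config <- function(genome_length = 100000, contig_name = "chrS",
                       snp_rate = 1e-3, indel_rate = 2e-4, max_indel = 10,
                       het_fraction = 0.6,
                       error_mismatch = 0.05, error_insertion = 0.03,
                       error_deletion = 0.03,
                       read_length_mean = 2000, depth = 30, seed = 1) {
  stopifnot(genome_length > 1000, max_indel >= 1, max_indel <= 16,
            depth > 0, read_length_mean > 300,
            all(c(snp_rate, indel_rate, het_fraction, error_mismatch,
                  error_insertion, error_deletion) >= 0),
            all(c(snp_rate, indel_rate, het_fraction, error_mismatch,
                  error_insertion, error_deletion) <= 1))
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a diploid genome with planted variants
#'
#' Variants are planted at the configured per-bp rates, kept at least
#' `2 * max_indel` bp apart (and out of the first/last 300 bp), and applied
#' to two haplotypes. Heterozygous variants go to one haplotype chosen at
#' random; homozygous variants to both.
#'
#' @param cfg a [sim_config()]
#' @return list with `ref` (a `reference`), `hap1`/`hap2` (character
#'   sequences), and `truth` (VCF-style data.frame, 0-based pos)
#' @export
simulate_genome <- function(cfg) {
  set.seed(derive_seed(cfg$seed, 1L))
  L <- as.integer(cfg$genome_length)
  rchars <- sample(DNA_BASES, L, replace = TRUE)
  margin <- 300L
  interior <- (margin + 1L):(L - margin)   # 1-based candidate rows
  is_snp <- stats::runif(length(interior)) < cfg$snp_rate
  is_ind <- stats::runif(length(interior)) < cfg$indel_rate
  pos1 <- interior[is_snp | is_ind]
  type <- ifelse(is_ind[is_snp | is_ind], "indel", "snp")  # indel wins ties
  # enforce spacing: greedy left-to-right
  keep <- logical(length(pos1))
  last <- -1e9
  for (i in seq_along(pos1)) {
    if (pos1[i] - last >= 2L * cfg$max_indel + 2L) { keep[i] <- TRUE
      last <- pos1[i] }
  }
  pos1 <- pos1[keep]; type <- type[keep]
  n <- length(pos1)
  recs <- vector("list", n)
  for (i in seq_len(n)) {
    p1 <- pos1[i]
    rb <- rchars[p1]
    het <- stats::runif(1) < cfg$het_fraction
    hap <- if (het) sample(1:2, 1) else 0L       # 0 = both
    if (type[i] == "snp") {
      alt <- sample(setdiff(DNA_BASES, rb), 1)
      ref_a <- rb
    } else {
      len <- min(cfg$max_indel, 1L + stats::rgeom(1, 0.45))
      if (stats::runif(1) < 0.5) {               # insertion after p1
        alt <- paste0(rb, paste(sample(DNA_BASES, len, replace = TRUE),
                                collapse = ""))
        ref_a <- rb
      } else {                                   # deletion of len bases
        ref_a <- paste(rchars[p1:(p1 + len)], collapse = "")
        alt <- rb
      }
    }
    recs[[i]] <- data.frame(
      contig = cfg$contig_name, pos = p1 - 1L, ref = ref_a, alt = alt,
      gt = if (!het) "1/1" else "0/1", hap = hap,
      stringsAsFactors = FALSE)
  }
  truth <- if (n) do.call(rbind, recs) else
    data.frame(contig = character(0), pos = integer(0), ref = character(0),
               alt = character(0), gt = character(0), hap = integer(0),
               stringsAsFactors = FALSE)
  refseq <- paste(rchars, collapse = "")
  ref <- reference_from_seqs(stats::setNames(refseq, cfg$contig_name))
  list(ref = ref,
       hap1 = apply_variants(rchars, truth, 1L),
       hap2 = apply_variants(rchars, truth, 2L),
       truth = truth)
}

# Apply planted variants carried by haplotype h (hap == 0 means both).
apply_variants <- function(rchars, truth, h) {
  if (!nrow(truth)) return(paste(rchars, collapse = ""))
  tr <- truth[truth$hap == 0L | truth$hap == h, , drop = FALSE]
  if (!nrow(tr)) return(paste(rchars, collapse = ""))
  tr <- tr[order(tr$pos), , drop = FALSE]
  out <- character(2L * nrow(tr) + 1L)
  cur <- 1L   # next untouched 1-based ref position
  for (i in seq_len(nrow(tr))) {
    p1 <- tr$pos[i] + 1L
    out[2L * i - 1L] <- paste(rchars[cur:(p1 - 1L)], collapse = "")
    out[2L * i] <- tr$alt[i]
    cur <- p1 + nchar(tr$ref[i])
  }
  out[2L * nrow(tr) + 1L] <- paste(rchars[cur:length(rchars)], collapse = "")
  paste(out, collapse = "")
}

#' Simulate aligned ONT-like reads from a diploid genome
#'
#' Reads alternate between the two haplotypes, carry the planted variants of
#' their haplotype plus per-base sequencing errors, and are emitted with the
#' true alignment in the CIGAR (no mapping step). Read starts are uniform, so
#' interior coverage is flat at `cfg$depth`.
#'
#' @param genome output of [simulate_genome()]
#' @param cfg the same [sim_config()]
#' @return a `read_set`
#' @export
simulate_reads <- function(genome, cfg) {
  set.seed(derive_seed(cfg$seed, 2L))
  L <- contig_length(genome$ref, cfg$contig_name)
  rchars <- genome$ref$chars[[cfg$contig_name]]
  mean_len <- cfg$read_length_mean
  n <- ceiling(cfg$depth * L / mean_len * 1.08)  # slight surplus for clipping
  lens <- 300L + stats::rgeom(n, 1 / (mean_len - 300))
  starts <- floor(stats::runif(n, -lens + 50, L - 50))
  hap <- rep_len(c(1L, 2L), n)
  strand <- ifelse(stats::runif(n) < 0.5, "+", "-")
  tr <- genome$truth
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    s0 <- max(0L, as.integer(starts[i]))
    e0 <- min(L, as.integer(starts[i] + lens[i]))
    if (e0 - s0 < 100L) next
    rd <- build_read(rchars, tr, hap[i], s0, e0, cfg)
    if (is.null(rd)) next
    rows[[i]] <- data.frame(
      qname = sprintf("r%06d", i), contig = cfg$contig_name, pos = rd$pos,
      strand = strand[i], cigar = rd$cigar, seq = rd$seq,
      stringsAsFactors = FALSE)
  }
  read_set(do.call(rbind, rows[!vapply(rows, is.null, logical(1))]))
}

# Construct one read covering reference window [s0, e0) from haplotype h,
# with planted variants and injected errors, returning pos/cigar/seq.
build_read <- function(rchars, truth, h, s0, e0, cfg) {
  idx <- (s0 + 1L):e0                 # 1-based ref rows
  w <- rchars[idx]
  npos <- length(idx)
  base_op <- rep.int("M", npos)       # per-ref-position op: M or D
  ins_after <- character(npos)        # inserted sequence after each position
  if (nrow(truth)) {
    tr <- truth[(truth$hap == 0L | truth$hap == h) &
                  truth$pos >= s0 & truth$pos + nchar(truth$ref) <= e0, ,
                drop = FALSE]
    for (j in seq_len(nrow(tr))) {
      rel <- tr$pos[j] - s0 + 1L
      nr <- nchar(tr$ref[j]); na <- nchar(tr$alt[j])
      if (nr == 1L && na == 1L) {
        w[rel] <- tr$alt[j]
      } else if (na > nr) {           # insertion (anchored at rel)
        ins_after[rel] <- substring(tr$alt[j], 2L)
      } else {                        # deletion of nr-1 bases after anchor
        base_op[(rel + 1L):(rel + nr - 1L)] <- "D"
      }
    }
  }
  # sequencing errors on non-deleted, non-variant-altered positions
  u <- stats::runif(npos)
  mis <- which(u < cfg$error_mismatch & base_op == "M")
  if (length(mis)) {
    shift <- sample(1:3, length(mis), replace = TRUE)
    w[mis] <- DNA_BASES[(match(w[mis], DNA_BASES) - 1L + shift) %% 4L + 1L]
  }
  u2 <- stats::runif(npos)
  edel <- which(u2 < cfg$error_deletion & base_op == "M")
  if (length(edel)) base_op[edel] <- "D"
  u3 <- stats::runif(npos)
  eins <- which(u3 < cfg$error_insertion)
  if (length(eins))
    ins_after[eins] <- paste0(ins_after[eins],
                              sample(DNA_BASES, length(eins), replace = TRUE))
  # trim leading/trailing deletions
  mm <- which(base_op == "M")
  if (length(mm) < 50L) return(NULL)
  a <- mm[1]; b <- mm[length(mm)]
  w <- w[a:b]; base_op <- base_op[a:b]; ins_after <- ins_after[a:b]
  pos <- s0 + a - 1L
  # sequence: kept bases plus insertions
  piece <- ifelse(base_op == "M", w, "")
  seq <- paste(paste0(piece, ins_after), collapse = "")
  # cigar: interleave per-position base op with insertion ops, then run-merge
  ilen <- nchar(ins_after)
  ops <- as.vector(rbind(base_op, ifelse(ilen > 0L, "I", NA)))
  lens <- as.vector(rbind(1L, ilen))
  keep <- !is.na(ops)
  ops <- ops[keep]; lens <- lens[keep]
  grp <- cumsum(c(TRUE, ops[-1] != ops[-length(ops)]))
  rl <- vapply(split(lens, grp), sum, numeric(1))
  ro <- ops[!duplicated(grp)]
  list(pos = pos, cigar = paste0(as.integer(rl), ro, collapse = ""), seq = seq)
}

#' Write simulator outputs to disk
#'
#' Produces FASTA (+fai), sorted indexed BAM, truth VCF, and a BED of the
#' confident region (the contig minus 200 bp at each edge).
#'
#' @param genome output of [simulate_genome()]
#' @param aln a `read_set` from [simulate_reads()]
#' @param dir output directory (created if needed)
#' @param prefix file name prefix
#' @return named list of file paths
#' @export
write_simulation <- function(genome, aln, dir, prefix = "sim") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fa <- file.path(dir, paste0(prefix, ".fa"))
  write_reference(genome$ref, fa)
  bam <- write_bam(aln, genome$ref, file.path(dir, paste0(prefix, ".bam")))
  vcf <- file.path(dir, paste0(prefix, ".truth.vcf"))
  tr <- genome$truth
  if (nrow(tr)) { tr$qual <- 60; tr$filter <- "PASS" }
  write_vcf(tr, genome$ref, vcf)
  bed <- file.path(dir, paste0(prefix, ".confident.bed"))
  L <- genome$ref$lengths[[1]]
  writeLines(sprintf("%s\t%d\t%d", names(genome$ref$lengths)[1], 200L,
                     L - 200L), bed)
  list(fasta = fa, bam = bam, truth_vcf = vcf, bed = bed)
}
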