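# Decoding caller probabilities to variant calls, and VCF round-trips.

onehotv <- function(k, i) { v <- numeric(k); v[i + 1] <- 1; v }

probs_for <- function(gt21, zyg, len1 = 16L, len2 = 16L) {
  list(gt21 = onehotv(21, gt21), zygosity = onehotv(3, zyg),
       len1 = onehotv(33, len1), len2 = onehotv(33, len2))
}

gt21_idx <- function(a, b) {
  tab <- genotype_class_table()
  o <- order(match(c(a, b), c("A", "C", "G", "T", "Ins", "Del")))
  p <- c(a, b)[o]
  which(tab$a1 == p[1] & tab$a2 == p[2]) - 1L
}

test_that("genotype class table enumerates the 21 unordered pairs", {
  tab <- genotype_class_table()
  expect_equal(nrow(tab), 21)
  # brute-force enumeration oracle
  sym <- c("A", "C", "G", "T", "Ins", "Del")
  brute <- expand.grid(i = 1:6, j = 1:6)
  brute <- brute[brute$i <= brute$j, ]
  got <- paste(tab$a1, tab$a2)
  want <- paste(sym[brute$i], sym[brute$j])
  expect_setequal(got, want)
  expect_equal(sum(got == "A A"), 1)
  expect_equal(sum(got == "Ins Del"), 1)
  expect_false(any(duplicated(got)))
})

test_that("hom-ref zygosity decodes to no call", {
  ref <- toy_reference(paste(rep("ACGT", 10), collapse = ""))
  site <- candidate_site_df("chrT", 10, "G")
  expect_null(decode_site(probs_for(gt21_idx("G", "G"), 0L), site, NULL,
                          ref))
})

test_that("het SNP decodes to ALT with GT 0/1", {
  ref <- toy_reference(paste(rep("A", 40), collapse = ""))
  site <- candidate_site_df("chrT", 10, "A")
  cl <- decode_site(probs_for(gt21_idx("A", "C"), 1L), site, NULL, ref)
  expect_equal(cl$ref, "A")
  expect_equal(cl$alt, "C")
  expect_equal(cl$gt, "0/1")
  expect_gt(cl$qual, 50)
  # hom-alt
  cl2 <- decode_site(probs_for(gt21_idx("C", "C"), 2L), site, NULL, ref)
  expect_equal(cl2$gt, "1/1")
  expect_equal(cl2$alt, "C")
  # multi-allelic het
  cl3 <- decode_site(probs_for(gt21_idx("C", "G"), 1L), site, NULL, ref)
  expect_equal(cl3$gt, "1/2")
  expect_setequal(strsplit(cl3$alt, ",")[[1]], c("C", "G"))
})

test_that("insertion uses the consensus inserted sequence among reads", {
  # reads carrying a 3-bp insertion AAT after pos 10 (T): T -> TAAT
  refseq <- paste(rep("ACGTT", 8), collapse = "")
  ref <- toy_reference(refseq)
  ins_reads <- toy_reads(pos = rep(5, 6), cigar = c(rep("6M3I6M", 4),
                                                    rep("12M", 2)),
                         seq = c(rep(paste0(substr(refseq, 6, 11), "AAT",
                                            substr(refseq, 12, 17)), 4),
                                 rep(substr(refseq, 6, 17), 2)))
  site <- candidate_site_df("chrT", 10, substr(refseq, 11, 11))
  cl <- decode_site(probs_for(gt21_idx(site$ref_base, "Ins"), 1L,
                              len1 = 16L, len2 = 19L),
                    site, ins_reads, ref)
  expect_equal(cl$alt, paste0(site$ref_base, "AAT"))
  expect_equal(cl$gt, "0/1")
})

test_that("deletion reconstructs the reference span", {
  refseq <- "ACGTAGTACGTACGTACGT"
  ref <- toy_reference(refseq)
  site <- candidate_site_df("chrT", 4, "A")   # AGT -> A (delete GT)
  cl <- decode_site(probs_for(gt21_idx("Del", "Del"), 2L, len1 = 14L,
                              len2 = 14L), site, NULL, ref)
  expect_equal(cl$ref, "AGT")
  expect_equal(cl$alt, "A")
  expect_equal(cl$gt, "1/1")
})

test_that("decode_site is total over all 21 x 3 argmax combinations", {
  ref <- toy_reference(paste(rep("ACGT", 20), collapse = ""))
  site <- candidate_site_df("chrT", 40, "A")
  for (g in 0:20) for (z in 0:2) {
    cl <- decode_site(probs_for(g, z), site, NULL, ref)
    if (z == 0) {
      expect_null(cl)
    } else if (!is.null(cl)) {
      alts <- strsplit(cl$alt, ",")[[1]]
      expect_true(all(alts != cl$ref))
      expect_true(cl$gt %in% c("0/1", "1/1", "1/2"))
    }
  }
  # extreme length indices stay within the flank (clip + filter flag)
  cl <- decode_site(probs_for(gt21_idx("A", "Ins"), 1L, len1 = 16L,
                              len2 = 32L), site, NULL, ref)
  expect_lte(nchar(cl$alt), 18)
})

test_that("qual is capped at 60 and reflects confidence", {
  ref <- toy_reference(paste(rep("A", 40), collapse = ""))
  site <- candidate_site_df("chrT", 10, "A")
  soft <- probs_for(gt21_idx("A", "C"), 1L)
  soft$zygosity <- c(0.2, 0.6, 0.2)
  cl <- decode_site(soft, site, NULL, ref)
  expect_lt(cl$qual, 10)
  hard <- probs_for(gt21_idx("A", "C"), 1L)
  expect_equal(decode_site(hard, site, NULL, ref)$qual, 60)
})

test_that("VCF writing round-trips through reading", {
  ref <- toy_reference(paste(rep("ACGT", 10), collapse = ""), "chrV")
  calls <- data.frame(
    contig = "chrV", pos = c(24L, 3L, 11L),   # unsorted on purpose
    ref = c("A", "TACG", "G"), alt = c("C", "T", "GTT"),
    gt = c("0/1", "1/1", "0/1"), qual = c(60, 31.7, 12),
    filter = c("PASS", "PASS", "lowqual"), stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".vcf")
  write_vcf(calls, ref, path)
  back <- read_vcf(path)
  expect_equal(back$pos, sort(calls$pos))                  # sorted output
  o <- order(calls$pos)
  expect_equal(back$ref, calls$ref[o])
  expect_equal(back$alt, calls$alt[o])
  expect_equal(back$gt, calls$gt[o])
  expect_equal(back$qual, calls$qual[o], tolerance = 0.01)
  # empty call set -> valid header-only file
  p2 <- tempfile(fileext = ".vcf")
  write_vcf(calls[0, ], ref, p2)
  lines <- readLines(p2)
  expect_true(any(startsWith(lines, "##fileformat=VCFv4.2")))
  expect_equal(nrow(read_vcf(p2)), 0)
})

test_that("written VCF parses with a standard external parser", {
  skip_if_not_installed("VariantAnnotation")
  ref <- toy_reference(paste(rep("ACGT", 10), collapse = ""), "chrV")
  calls <- data.frame(contig = "chrV", pos = 5L, ref = "A", alt = "T",
                      gt = "0/1", qual = 42, filter = "PASS",
                      stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".vcf")
  write_vcf(calls, ref, path)
  v <- VariantAnnotation::readVcf(path)
  expect_equal(length(v), 1L)
  expect_equal(as.integer(BiocGenerics::start(v)), 6L)  # 1-based POS
})

test_that("call_region on a clean region returns nothing", {
  sim <- small_sim(seed = 21, genome_length = 4000, depth = 15,
                   snp_rate = 0, indel_rate = 0, error_mismatch = 0,
                   error_insertion = 0, error_deletion = 0)
  gp <- init_generator(1); cp <- init_caller(1)
  calls <- call_region(gp, cp, sim$aln, sim$genome$ref,
                       genome_region("chrS", 300, 3700))
  expect_equal(nrow(calls), 0)
})
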