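# Featurization: candidate scanning, pileup tensors, flattening, labeling.

test_that("hand-enumerated 3-read stack produces the expected counts", {
  ref <- toy_reference("ACGT")
  # three forward reads over the whole contig; read 2 has C->T at offset 1
  aln <- toy_reads(pos = c(0, 0, 0), cigar = "4M",
                   seq = c("ACGT", "ATGT", "ACGT"))
  t <- build_pileup_tensor(aln, candidate_site_df("chrT", 1, "C"), ref,
                           flank = 2)
  a <- t$data   # 5 x 8 x 4 window centered on pos 1
  # channel 1 (ref match): A:3 at window col 2 (pos 0), C:2 at col 3, ...
  expect_equal(a[2, 1, 1], 3)   # A matches at pos 0
  expect_equal(a[3, 2, 1], 2)   # C matches at pos 1
  expect_equal(a[4, 3, 1], 3)   # G at pos 2
  expect_equal(a[5, 4, 1], 3)   # T at pos 3
  expect_equal(a[3, 4, 4], 1)   # T mismatch at pos 1, SNV channel
  expect_equal(sum(a[, , 2]), 0)
  expect_equal(sum(a[, , 3]), 0)
  expect_equal(sum(a), 3 + 2 + 3 + 3 + 1)
})

test_that("window with no reads is all zero and padding works at edges", {
  ref <- toy_reference(paste(rep("ACGT", 30), collapse = ""))
  aln <- toy_reads(pos = 0, cigar = "4M", seq = "ACGT")
  t <- build_pileup_tensor(aln, candidate_site_df("chrT", 80, "A"), ref)
  expect_equal(dim(t$data), c(33, 8, 4))
  expect_true(all(t$data == 0))
  # near the left contig edge: out-of-range columns are zero padding
  t2 <- build_pileup_tensor(aln, candidate_site_df("chrT", 2, "G"), ref)
  expect_equal(dim(t2$data), c(33, 8, 4))
  expect_equal(sum(t2$data), 4)
})

test_that("flatten maps (b, s) to column 4*(b-1)+s, losslessly", {
  z <- array(0, c(33, 8, 4))
  expect_equal(flatten_tensor(z), matrix(0, 33, 32), ignore_attr = TRUE)
  t1 <- array(0, c(33, 8, 4))
  t1[1, 2, 3] <- 7          # 0-based (0,1,2) -> image[0, 4*1+2] (0-based)
  img <- flatten_tensor(t1)
  expect_equal(img[1, 7], 7)
  expect_equal(sum(img), 7)
  for (s in 1:20) {
    tt <- random_tensor(s)
    expect_identical(unflatten_image(flatten_tensor(tt)), tt)
  }
})

test_that("tensor counts equal the brute-force per-read oracle", {
  sim <- small_sim(seed = 3)
  reg <- genome_region("chrS", 300, 5700)
  sites <- scan_candidates(sim$aln, reg, sim$genome$ref)
  expect_gt(nrow(sites), 20)
  set.seed(1)
  pick <- sites[sample(nrow(sites), 20), ]
  for (i in seq_len(nrow(pick))) {
    t <- build_pileup_tensor(sim$aln, pick[i, ], sim$genome$ref)
    bf <- brute_force_tensor(sim$aln, sim$genome$ref, "chrS", pick[i, ]$pos)
    expect_equal(t$data, bf)
  }
})

test_that("forward-only input leaves reverse-strand rows empty (and vice versa)", {
  ref <- toy_reference(paste(rep("ACGT", 20), collapse = ""))
  fwd <- toy_reads(pos = c(0, 8, 16), cigar = "12M",
                   seq = substr(ref$seqs[[1]], 1, 12), strand = "+")
  revs <- toy_reads(pos = c(0, 8, 16), cigar = "12M",
                    seq = substr(ref$seqs[[1]], 1, 12), strand = "-")
  tf <- build_pileup_tensor(fwd, candidate_site_df("chrT", 10, "G"), ref)
  tr <- build_pileup_tensor(revs, candidate_site_df("chrT", 10, "G"), ref)
  expect_true(all(tf$data[, 5:8, ] == 0))
  expect_gt(sum(tf$data[, 1:4, ]), 0)
  expect_true(all(tr$data[, 1:4, ] == 0))
  expect_gt(sum(tr$data[, 5:8, ]), 0)
})

test_that("scan_candidates applies the allele-fraction and depth screens", {
  ref <- toy_reference("AAAAAAAAAA")
  # 10 reads over one base at pos 4; two carry a mismatch
  aln <- toy_reads(pos = rep(4, 10), cigar = "1M",
                   seq = c(rep("C", 2), rep("A", 8)))
  reg <- genome_region("chrT", 0, 10)
  s <- scan_candidates(aln, reg, ref, min_af = 0.2)
  expect_equal(nrow(s), 1)
  expect_equal(s$pos, 4)
  expect_equal(s$depth, 10)
  expect_equal(s$alt_fraction, 0.2)
  # all-reference stack yields nothing
  clean <- toy_reads(pos = rep(4, 10), cigar = "1M", seq = "A")
  expect_equal(nrow(scan_candidates(clean, reg, ref)), 0)
  # raising min_af never adds sites (monotonicity)
  sim <- small_sim(seed = 5)
  reg2 <- genome_region("chrS", 300, 4000)
  afs <- c(0.1, 0.2, 0.3, 0.5)
  counts <- vapply(afs, function(a)
    nrow(scan_candidates(sim$aln, reg2, sim$genome$ref, min_af = a)),
    numeric(1))
  expect_true(all(diff(counts) <= 0))
  pos_hi <- scan_candidates(sim$aln, reg2, sim$genome$ref, min_af = 0.4)$pos
  pos_lo <- scan_candidates(sim$aln, reg2, sim$genome$ref, min_af = 0.2)$pos
  expect_true(all(pos_hi %in% pos_lo))
})

test_that("planted het SNP at 30x with no errors is recovered at af ~ 0.5", {
  sim <- small_sim(seed = 11, depth = 30, error_mismatch = 0,
                   error_insertion = 0, error_deletion = 0,
                   snp_rate = 2e-3, indel_rate = 0, het_fraction = 1)
  reg <- genome_region("chrS", 300, 5700)
  s <- scan_candidates(sim$aln, reg, sim$genome$ref)
  truth_pos <- sim$genome$truth$pos
  truth_pos <- truth_pos[truth_pos >= 300 & truth_pos < 5700]
  expect_gt(length(truth_pos), 3)
  expect_setequal(s$pos, truth_pos)
  # binomial check: alt fraction within 3 sigma of Binomial(depth, 0.5)/depth
  for (i in seq_len(nrow(s))) {
    sd3 <- 3 * sqrt(0.25 / s$depth[i])
    expect_lt(abs(s$alt_fraction[i] - 0.5), sd3 + 1e-9)
  }
})

test_that("label_site encodes hom-ref, het insertion, hom deletion", {
  site <- candidate_site_df("chrT", 5, "G")
  hr <- label_site(site, NULL)
  tab <- genotype_class_table()
  expect_equal(hr$zygosity, 0L)
  expect_equal(tab[hr$gt21 + 1, ], data.frame(a1 = "G", a2 = "G"),
               ignore_attr = TRUE)
  expect_equal(hr$len1, 16L)
  expect_equal(hr$len2, 16L)
  # heterozygous insertion T -> TAAT
  ins <- label_site(candidate_site_df("chrT", 5, "T"),
                    rec(5, "T", "TAAT", c(0L, 1L)))
  expect_equal(ins$zygosity, 1L)
  expect_true("Ins" %in% unlist(tab[ins$gt21 + 1, ]))
  expect_setequal(c(ins$len1, ins$len2), c(16L, 19L))
  # homozygous deletion AGT -> A
  del <- label_site(candidate_site_df("chrT", 5, "A"),
                    rec(5, "AGT", "A", c(1L, 1L)))
  expect_equal(del$zygosity, 2L)
  expect_equal(del$len1, 14L)
  expect_equal(del$len2, 14L)
  expect_equal(tab[del$gt21 + 1, ], data.frame(a1 = "Del", a2 = "Del"),
               ignore_attr = TRUE)
  # non-ACGT truth alleles are rejected with a warning -> hom-ref
  expect_warning(bad <- label_site(site, rec(5, "G", "<DEL>", c(0L, 1L))),
                 "non-ACGT")
  expect_equal(bad$zygosity, 0L)
})

test_that("make_training_pairs pairs sites, labels and both depths", {
  sim <- small_sim(seed = 13, genome_length = 4000, depth = 25)
  tr <- sim$genome$truth
  reg <- genome_region("chrS", 300, 3700)
  low <- downsample(sim$aln, 0.4, seed = 1)
  ds <- make_training_pairs(low, sim$aln, tr, reg, sim$genome$ref)
  expect_gt(length(ds), 5)
  pos <- vapply(ds, function(e) e$site$pos, integer(1))
  expect_true(!is.unsorted(pos))
  # truth sites in region are always included
  tpos <- tr$pos[tr$pos >= 300 & tr$pos < 3700]
  expect_true(all(tpos %in% pos))
  # identical alignments give identical image pairs
  ds2 <- make_training_pairs(sim$aln, sim$aln, tr, reg, sim$genome$ref)
  for (e in ds2) expect_equal(e$low_image, e$high_image)
  # with no truth, every label is hom-ref
  ds3 <- make_training_pairs(low, sim$aln, NULL, reg, sim$genome$ref)
  expect_true(all(vapply(ds3, function(e) e$label$zygosity, integer(1)) == 0L))
})
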