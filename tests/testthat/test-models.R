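# Network contracts: shapes, ranges, determinism, and overfit capacity.

test_that("generator preserves shape and stays finite", {
  gp <- init_generator(1)
  set.seed(1)
  imgs <- lapply(1:3, function(i) matrix(rpois(33 * 32, 3), 33, 32))
  out <- generator_forward(gp, imgs)$out
  expect_equal(dim(out), c(1L, 33L * 32L * 3L))
  expect_true(all(is.finite(out)))
  # all-zero input also yields finite output
  z <- generator_forward(gp, matrix(0, 1, 33 * 32))$out
  expect_true(all(is.finite(z)))
  # shape contract violation
  expect_error(generator_forward(gp, matrix(0, 1, 100)))
})

test_that("discriminator output is a probability, deterministically", {
  dp <- init_discriminator(2)
  set.seed(2)
  for (i in 1:5) {
    a <- matrix(rpois(33 * 32, 4), 33, 32)
    b <- matrix(rpois(33 * 32, 4), 33, 32)
    p1 <- discriminator_forward(dp, list(a), list(b))$out
    expect_gt(p1, 0); expect_lt(p1, 1)
    expect_identical(p1, discriminator_forward(dp, list(a), list(b))$out)
  }
  # channel order is (candidate, conditioning): a one-hot probe in either
  # argument reaches different weights, so swapping generally changes output
  probe <- matrix(0, 33, 32); probe[17, 1] <- 50
  blank <- matrix(1, 33, 32)
  p_ab <- discriminator_forward(dp, list(probe), list(blank))$out
  p_ba <- discriminator_forward(dp, list(blank), list(probe))$out
  expect_false(isTRUE(all.equal(p_ab, p_ba)))
})

test_that("caller heads are simplices of sizes 21/3/33/33", {
  cp <- init_caller(3)
  set.seed(3)
  gen <- lapply(1:4, function(i) matrix(rexp(33 * 32), 33, 32))
  low <- lapply(1:4, function(i) matrix(rexp(33 * 32), 33, 32))
  pr <- caller_forward(cp, gen, low)$probs
  expect_equal(vapply(pr, nrow, integer(1)),
               c(gt21 = 21L, zygosity = 3L, len1 = 33L, len2 = 33L))
  for (h in pr) {
    expect_true(all(h >= 0))
    expect_true(all(abs(colSums(h) - 1) < 1e-5))
  }
  # deterministic forward
  pr2 <- caller_forward(cp, gen, low)$probs
  expect_identical(pr, pr2)
})

test_that("seeded initialization is reproducible and seed-sensitive", {
  expect_identical(init_generator(5), init_generator(5))
  expect_false(identical(init_generator(5)$enc1a_W,
                         init_generator(6)$enc1a_W))
  expect_identical(init_caller(5), init_caller(5))
  expect_identical(init_discriminator(5), init_discriminator(5))
})

test_that("generator can overfit a single low/high pair", {
  # fitting one pair: MSE after training must fall below 1% of the initial
  # error (reduced step count; convergence is fast on a single pair)
  sim <- small_sim(seed = 51, genome_length = 5000, depth = 30)
  low <- downsample(sim$aln, 1 / 3, seed = 51)
  reg <- genome_region("chrS", 300, 4700)
  sites <- scan_candidates(low, reg, sim$genome$ref)
  p <- sites$pos[which.max(sites$depth)]
  li <- depthlift:::window_image(low, sim$genome$ref, "chrS", p)
  hi <- depthlift:::window_image(sim$aln, sim$genome$ref, "chrS", p)
  X <- depthlift:::as_batch_matrix(list(li))
  Hi <- depthlift:::as_batch_matrix(list(hi))
  gp <- init_generator(7)
  opt <- depthlift:::adam_init(gp)
  mse0 <- mean((generator_forward(gp, X)$out - Hi)^2)
  for (i in 1:500) {
    fw <- generator_forward(gp, X, want_cache = TRUE)
    dY <- 2 * (fw$out - Hi) / length(Hi)
    gr <- generator_backward(gp, fw$cache, dY)
    upd <- depthlift:::adam_step(gp, gr, opt, 3e-3)
    gp <- upd$params; opt <- upd$state
  }
  mse1 <- mean((generator_forward(gp, X)$out - Hi)^2)
  expect_lt(mse1, 0.01 * mse0)
})

test_that("discriminator separates a trivially separable toy set", {
  # real = constant 10 images, fake = constant 0; D alone reaches 100%
  real <- lapply(1:8, function(i) matrix(10, 33, 32))
  fake <- lapply(1:8, function(i) matrix(0, 33, 32))
  cond <- lapply(1:8, function(i) matrix(1, 33, 32))
  dp <- init_discriminator(9)
  opt <- depthlift:::adam_init(dp)
  for (i in 1:80) {
    dr <- discriminator_forward(dp, real, cond, want_cache = TRUE,
                                slot = 0L)
    df <- discriminator_forward(dp, fake, cond, want_cache = TRUE,
                                slot = 1L)
    n <- 8
    dPr <- -1 / (n * pmax(dr$out, 1e-7))
    dPf <- 1 / (n * pmax(1 - df$out, 1e-7))
    gr <- discriminator_backward(dp, 0L, dPr)$grads
    gf <- discriminator_backward(dp, 1L, dPf)$grads
    upd <- depthlift:::adam_step(dp, Map(`+`, gr, gf), opt, 3e-3)
    dp <- upd$params; opt <- upd$state
  }
  p_real <- discriminator_forward(dp, real, cond)$out
  p_fake <- discriminator_forward(dp, fake, cond)$out
  expect_true(all(p_real > 0.5))
  expect_true(all(p_fake < 0.5))
})

test_that("caller learns zygosity on a balanced error-free fixture", {
  # error-free high-depth simulation is a fully solvable problem; a
  # balanced subset must be classified nearly perfectly after training
  # (desk-scale reduction of the 200-example / 300-step setting)
  cfg <- sim_config(genome_length = 16000, depth = 30, seed = 53,
                    snp_rate = 8e-3, indel_rate = 0, error_mismatch = 0,
                    error_insertion = 0, error_deletion = 0)
  genome <- simulate_genome(cfg)
  aln <- simulate_reads(genome, cfg)
  tr <- genome$truth; tr$qual <- 60; tr$filter <- "PASS"
  ds <- make_training_pairs(aln, aln, tr, genome_region("chrS", 300, 15700),
                            genome$ref)
  zyg <- vapply(ds, function(e) e$label$zygosity, integer(1))
  set.seed(53)
  # include every variant plus an equal number of hom-ref sites (if any)
  pos_idx <- which(zyg > 0)
  neg_idx <- which(zyg == 0)
  sel <- c(pos_idx, sample(neg_idx, min(length(neg_idx), length(pos_idx))))
  ds <- ds[sel]
  expect_gt(length(ds), 40)
  bt <- depthlift:::batch_tensors(ds)
  cp <- init_caller(53)
  opt <- depthlift:::adam_init(depthlift:::prefix_names(cp, "C."))
  gp <- init_generator(53); dp <- init_discriminator(53)
  cfg_t <- train_config(batch_size = length(ds), seed = 53,
                        mode = "caller_only")
  w <- loss_weights()
  st <- list(c_params = cp, opt_gc = opt)
  for (i in 1:250) {
    r <- train_step(bt, gp, st$c_params, dp, w, st$opt_gc,
                    depthlift:::adam_init(dp), cfg_t)
    st <- list(c_params = r$c_params, opt_gc = r$opt_gc)
  }
  pr <- caller_forward(st$c_params, bt$low, bt$low)$probs
  acc <- mean((apply(pr$zygosity, 2, which.max) - 1L) == bt$zygosity)
  expect_gt(acc, 0.95)
})
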