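# The three networks: generator G (encoder-decoder with skip connections and
# dilated convolutions), conditional discriminator D (G's encoder + global
# average pooling + sigmoid unit), and multi-task caller C (2-layer BiLSTM
# over the 33 window positions + two affine layers + four softmax heads of
# sizes 21/3/33/33).
#
# Parameters are flat named lists of arrays; forward passes return the output
# together with a cache consumed by the matching backward pass. Everything is
# deterministic given parameters and input.

IMG_H <- 33L
IMG_W <- 32L

#' Initialize generator parameters
#'
#' Encoder stages at 16/32/64 channels (each: 3x3 conv d=1, 3x3 conv d=2,
#' 2x2 max pool), a 64-channel bottleneck, and a mirrored decoder
#' (2x transposed conv, skip concatenation, conv d=1, conv d=2) followed by a
#' linear 1x1 projection to one channel. Rectifier activations; no
#' normalization layers. Seeded uniform fan-in initialization. Convolution
#' weights are stored as (9*Cin, Cout) matrices (kernel-offset row blocks),
#' transposed convolutions as (4*Cin, Cout).
#'
#' @param seed integer seed
#' @return named list of parameter arrays of class `gen_params`
#' @export
init_generator <- function(seed = 1) {
  set.seed(derive_seed(seed, 11L))
  p <- list(
    enc1a_W = init_conv(1, 16), enc1a_b = numeric(16),
    enc1b_W = init_conv(16, 16), enc1b_b = numeric(16),
    enc2a_W = init_conv(16, 32), enc2a_b = numeric(32),
    enc2b_W = init_conv(32, 32), enc2b_b = numeric(32),
    enc3a_W = init_conv(32, 64), enc3a_b = numeric(64),
    enc3b_W = init_conv(64, 64), enc3b_b = numeric(64),
    bot_a_W = init_conv(64, 64), bot_a_b = numeric(64),
    bot_b_W = init_conv(64, 64), bot_b_b = numeric(64),
    up3_W = init_conv(64, 64, 4L), up3_b = numeric(64),
    dec3a_W = init_conv(128, 64), dec3a_b = numeric(64),
    dec3b_W = init_conv(64, 64), dec3b_b = numeric(64),
    up2_W = init_conv(64, 32, 4L), up2_b = numeric(32),
    dec2a_W = init_conv(64, 32), dec2a_b = numeric(32),
    dec2b_W = init_conv(32, 32), dec2b_b = numeric(32),
    up1_W = init_conv(32, 16, 4L), up1_b = numeric(16),
    dec1a_W = init_conv(32, 16), dec1a_b = numeric(16),
    dec1b_W = init_conv(16, 16), dec1b_b = numeric(16),
    out_W = init_mat(1, 16, 16), out_b = numeric(1))
  class(p) <- c("gen_params", "dl_params")
  p
}

#' Generator forward pass
#'
#' The computation runs in compiled code with all intermediate activations
#' held in a persistent context; the returned `cache = "cpp"` token marks
#' that context as valid for the next [generator_backward()] call.
#'
#' @param params from [init_generator()]
#' @param X images as a (1, 33*32*N) matrix, or a list of 33x32 matrices
#' @param want_cache keep the backward cache?
#' @return list(out = (1, 33*32*N) matrix, cache)
#' @export
generator_forward <- function(params, X, want_cache = FALSE) {
  X <- as_batch_matrix(X, 1L)
  N <- ncol(X) / (IMG_H * IMG_W)
  stopifnot(N == round(N))
  out <- .cpp_g_fwd(unclass(params), X, as.integer(N))
  list(out = out, cache = if (want_cache) "cpp" else NULL)
}

#' Generator backward pass
#'
#' @param params generator parameters
#' @param cache from `generator_forward(..., want_cache = TRUE)` (must be
#'   the most recent generator forward)
#' @param dY gradient w.r.t. the output image batch
#' @return named list of parameter gradients
#' @export
generator_backward <- function(params, cache, dY) {
  stopifnot(identical(cache, "cpp"))
  g <- .cpp_g_bwd(unclass(params), dY)
  g[["dX"]] <- NULL
  g[names(params)]
}

#' Initialize discriminator parameters
#'
#' Backbone mirrors the generator encoder but takes a 2-channel input (the
#' candidate image stacked with the conditioning low-depth image), then
#' global average pooling to a 64-vector and one sigmoid unit.
#'
#' @param seed integer seed
#' @return named list of class `disc_params`
#' @export
init_discriminator <- function(seed = 1) {
  set.seed(derive_seed(seed, 12L))
  p <- list(
    enc1a_W = init_conv(2, 16), enc1a_b = numeric(16),
    enc1b_W = init_conv(16, 16), enc1b_b = numeric(16),
    enc2a_W = init_conv(16, 32), enc2a_b = numeric(32),
    enc2b_W = init_conv(32, 32), enc2b_b = numeric(32),
    enc3a_W = init_conv(32, 64), enc3a_b = numeric(64),
    enc3b_W = init_conv(64, 64), enc3b_b = numeric(64),
    fc_W = init_mat(1, 64, 64), fc_b = numeric(1))
  class(p) <- c("disc_params", "dl_params")
  p
}

#' Discriminator forward pass
#'
#' Channel order of the 2-channel input is (candidate, conditioning). Two
#' independent cache slots allow the real and the generated pass of one
#' training step to be backpropagated separately.
#'
#' @param params from [init_discriminator()]
#' @param candidate,conditioning (1, 33*32*N) matrices or lists of images
#' @param want_cache keep the backward cache?
#' @param slot cache slot (0 or 1)
#' @return list(out = probability vector of length N, cache)
#' @export
discriminator_forward <- function(params, candidate, conditioning,
                                  want_cache = FALSE, slot = 0L) {
  A <- as_batch_matrix(candidate, 1L)
  B <- as_batch_matrix(conditioning, 1L)
  stopifnot(ncol(A) == ncol(B))
  N <- as.integer(ncol(A) / (IMG_H * IMG_W))
  out <- .cpp_d_fwd(unclass(params), A, B, N, as.integer(slot))
  list(out = as.numeric(out), cache = if (want_cache) as.integer(slot) else
    NULL)
}

#' Discriminator backward pass
#'
#' @param params discriminator parameters
#' @param cache from `discriminator_forward(..., want_cache = TRUE)`
#' @param dP gradient w.r.t. the output probabilities (length N)
#' @return list(grads = parameter gradients, dCandidate, dConditioning =
#'   gradients w.r.t. the two input image batches)
#' @export
discriminator_backward <- function(params, cache, dP) {
  stopifnot(cache %in% c(0L, 1L))
  r <- .cpp_d_bwd(unclass(params), as.numeric(dP), cache)
  dA <- r[["dCandidate"]]; dB <- r[["dConditioning"]]
  r[["dCandidate"]] <- NULL; r[["dConditioning"]] <- NULL
  list(grads = r[names(params)], dCandidate = dA, dConditioning = dB)
}

#' Initialize caller parameters
#'
#' Two-layer bidirectional LSTM (hidden size 128 per direction) over the 33
#' window positions, each step seeing the 64 concatenated features of the
#' generated and low-depth images; the final-step states of both directions
#' (256 values) feed affine layers of width 192 and 96 and four softmax heads
#' of sizes 21, 3, 33, 33.
#'
#' @param seed integer seed
#' @return named list of class `caller_params`
#' @export
init_caller <- function(seed = 1) {
  set.seed(derive_seed(seed, 13L))
  H <- 128L
  mk <- function(fin) list(
    Wx = init_mat(4L * H, fin, fin),
    Wh = init_mat(4L * H, H, H),
    b = numeric(4L * H))
  l1f <- mk(64L); l1r <- mk(64L); l2f <- mk(256L); l2r <- mk(256L)
  p <- list(
    l1f_Wx = l1f$Wx, l1f_Wh = l1f$Wh, l1f_b = l1f$b,
    l1r_Wx = l1r$Wx, l1r_Wh = l1r$Wh, l1r_b = l1r$b,
    l2f_Wx = l2f$Wx, l2f_Wh = l2f$Wh, l2f_b = l2f$b,
    l2r_Wx = l2r$Wx, l2r_Wh = l2r$Wh, l2r_b = l2r$b,
    fc1_W = init_mat(192, 256, 256), fc1_b = numeric(192),
    fc2_W = init_mat(96, 192, 192), fc2_b = numeric(96),
    head_gt_W = init_mat(21, 96, 96), head_gt_b = numeric(21),
    head_zyg_W = init_mat(3, 96, 96), head_zyg_b = numeric(3),
    head_l1_W = init_mat(33, 96, 96), head_l1_b = numeric(33),
    head_l2_W = init_mat(33, 96, 96), head_l2_b = numeric(33))
  class(p) <- c("caller_params", "dl_params")
  p
}

# Build the (64, N, 33) caller input sequence from two image batches:
# step p's features are the 32 columns of the generated image at window
# position p followed by the 32 columns of the low-depth image.
caller_input_seq <- function(generated, low) {
  G <- as_batch_matrix(generated, 1L)
  Lw <- as_batch_matrix(low, 1L)
  N <- as.integer(ncol(G) / (IMG_H * IMG_W))
  ga <- array(G, c(IMG_H, IMG_W, N))      # hw fastest: h then w
  la <- array(Lw, c(IMG_H, IMG_W, N))
  X <- array(0, c(64L, N, IMG_H))
  X[1:32, , ] <- aperm(ga, c(2, 3, 1))
  X[33:64, , ] <- aperm(la, c(2, 3, 1))
  X
}

# Scatter a (64, N, 33) sequence gradient back onto the two image batches.
caller_input_seq_bwd <- function(dX) {
  N <- dim(dX)[2]
  dG <- aperm(dX[1:32, , , drop = FALSE], c(3, 1, 2))    # (33, 32, N)
  dL <- aperm(dX[33:64, , , drop = FALSE], c(3, 1, 2))
  dim(dG) <- c(1L, IMG_H * IMG_W * N)
  dim(dL) <- c(1L, IMG_H * IMG_W * N)
  list(dGenerated = dG, dLow = dL)
}

#' Caller forward pass
#'
#' @param params from [init_caller()]
#' @param generated,low image batches ((1, 33*32*N) matrices or lists)
#' @param want_cache keep the backward cache?
#' @return list(probs = list(gt21 (21 x N), zygosity (3 x N), len1, len2
#'   (33 x N)), logits, cache)
#' @export
caller_forward <- function(params, generated, low, want_cache = FALSE) {
  X <- caller_input_seq(generated, low)
  l1f <- .cpp_lstm_fwd(X, params$l1f_Wx, params$l1f_Wh, params$l1f_b,
                       FALSE, 0L)
  l1r <- .cpp_lstm_fwd(X, params$l1r_Wx, params$l1r_Wh, params$l1r_b,
                       TRUE, 1L)
  S1 <- abind_rows(l1f$out, l1r$out)      # (256, N, 33)
  l2f <- .cpp_lstm_fwd(S1, params$l2f_Wx, params$l2f_Wh, params$l2f_b,
                       FALSE, 2L)
  l2r <- .cpp_lstm_fwd(S1, params$l2r_Wx, params$l2r_Wh, params$l2r_b,
                       TRUE, 3L)
  # readout at the candidate position (window center): by then each
  # direction has consumed the center column, and the gradient path to the
  # classified site is short
  ctr <- (IMG_H + 1L) %/% 2L
  hh <- rbind(matrix(l2f$out[, , ctr], 128L),
              matrix(l2r$out[, , ctr], 128L))
  f1 <- dense_fwd(hh, params$fc1_W, params$fc1_b)
  r1 <- relu_fwd(f1$out)
  f2 <- dense_fwd(r1$out, params$fc2_W, params$fc2_b)
  r2 <- relu_fwd(f2$out)
  logits <- list(
    gt21 = dense_fwd(r2$out, params$head_gt_W, params$head_gt_b),
    zygosity = dense_fwd(r2$out, params$head_zyg_W, params$head_zyg_b),
    len1 = dense_fwd(r2$out, params$head_l1_W, params$head_l1_b),
    len2 = dense_fwd(r2$out, params$head_l2_W, params$head_l2_b))
  probs <- lapply(logits, function(l) softmax_cols(l$out))
  cache <- NULL
  if (want_cache)
    cache <- list(N = ncol(hh), f1 = f1,
                  r1 = r1, f2 = f2, r2 = r2, logits = logits)
  list(probs = probs, logits = lapply(logits, `[[`, "out"), cache = cache)
}

abind_rows <- function(A, B) {
  dA <- dim(A)
  out <- array(0, c(dA[1] + dim(B)[1], dA[2], dA[3]))
  out[seq_len(dA[1]), , ] <- A
  out[dA[1] + seq_len(dim(B)[1]), , ] <- B
  out
}

#' Caller backward pass
#'
#' @param params caller parameters
#' @param cache from `caller_forward(..., want_cache = TRUE)`
#' @param dlogits named list of gradients w.r.t. the four head logit matrices
#' @return list(grads, dGenerated, dLow)
#' @export
caller_backward <- function(params, cache, dlogits) {
  g <- zero_grads(params)
  heads <- list(gt21 = "head_gt", zygosity = "head_zyg", len1 = "head_l1",
                len2 = "head_l2")
  dr2 <- NULL
  for (nm in names(heads)) {
    hb <- dense_bwd(cache$logits[[nm]]$cache, dlogits[[nm]])
    g[[paste0(heads[[nm]], "_W")]] <- hb$dW
    g[[paste0(heads[[nm]], "_b")]] <- hb$db
    dr2 <- if (is.null(dr2)) hb$dX else dr2 + hb$dX
  }
  df2 <- relu_bwd(cache$r2$cache, dr2)
  b2 <- dense_bwd(cache$f2$cache, df2$dX)
  g$fc2_W <- b2$dW; g$fc2_b <- b2$db
  df1 <- relu_bwd(cache$r1$cache, b2$dX)
  b1 <- dense_bwd(cache$f1$cache, df1$dX)
  g$fc1_W <- b1$dW; g$fc1_b <- b1$db
  dhh <- b1$dX                            # (256, N)
  ctr <- (IMG_H + 1L) %/% 2L
  N <- cache$N
  dseq_f <- array(0, c(128L, N, IMG_H))
  dseq_f[, , ctr] <- dhh[1:128, , drop = FALSE]
  dseq_r <- array(0, c(128L, N, IMG_H))
  dseq_r[, , ctr] <- dhh[129:256, , drop = FALSE]
  d2f <- .cpp_lstm_bwd(params$l2f_Wx, params$l2f_Wh, dseq_f, NULL, 2L)
  d2r <- .cpp_lstm_bwd(params$l2r_Wx, params$l2r_Wh, dseq_r, NULL, 3L)
  g$l2f_Wx <- d2f$dWx; g$l2f_Wh <- d2f$dWh; g$l2f_b <- as.numeric(d2f$db)
  g$l2r_Wx <- d2r$dWx; g$l2r_Wh <- d2r$dWh; g$l2r_b <- as.numeric(d2r$db)
  dS1 <- d2f$dX + d2r$dX                  # (256, N, 33)
  d1f <- .cpp_lstm_bwd(params$l1f_Wx, params$l1f_Wh,
                       dS1[1:128, , , drop = FALSE], NULL, 0L)
  d1r <- .cpp_lstm_bwd(params$l1r_Wx, params$l1r_Wh,
                       dS1[129:256, , , drop = FALSE], NULL, 1L)
  g$l1f_Wx <- d1f$dWx; g$l1f_Wh <- d1f$dWh; g$l1f_b <- as.numeric(d1f$db)
  g$l1r_Wx <- d1r$dWx; g$l1r_Wh <- d1r$dWh; g$l1r_b <- as.numeric(d1r$db)
  din <- caller_input_seq_bwd(d1f$dX + d1r$dX)
  c(list(grads = g), din)
}

# Coerce a list of 33x32 image matrices (or an already-flat matrix) to the
# (C, H*W*N) batch layout.
as_batch_matrix <- function(x, C = 1L) {
  if (is.matrix(x) && nrow(x) == C && ncol(x) %% (IMG_H * IMG_W) == 0L &&
      !(nrow(x) == IMG_H && ncol(x) == IMG_W))
    return(x)
  if (is.matrix(x)) x <- list(x)
  stopifnot(all(vapply(x, function(m) all(dim(m) == c(IMG_H, IMG_W)),
                       logical(1))))
  matrix(unlist(lapply(x, as.numeric), use.names = FALSE), nrow = C)
}

zero_grads <- function(params) {
  lapply(unclass(params), function(p) {
    if (is.matrix(p) || is.array(p)) array(0, dim(p)) else numeric(length(p))
  })
}
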