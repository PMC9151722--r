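# Alternating two-optimizer training.
#
# Each step has two phases. Phase 1 runs G on the low-depth batch, scores
# the generated images with D (conditioned on the low image) and with the
# caller heads, and updates G and C jointly on
# lambda1*L_G + lambda2*L_C + lambda3*L_adver; D's parameters are frozen
# (the adversarial gradient flows through D into G only). Phase 2 evaluates
# D on (high, low) and on (generated-detached, low) and updates D on L_D.
# Both Adam optimizers take exactly one step per iteration.

#' Training configuration
#'
#' Defaults are the desk-scale profile (batch 256, 5 epochs); the published
#' training regime (batch 5000, up to 30 epochs, same learning rate) ships
#' as the "paper" profile in `inst/config/paper.json`.
#'
#' @param learning_rate Adam learning rate (default 3e-4), shared by both
#'   optimizers
#' @param batch_size mini-batch size
#' @param epochs number of passes over the dataset
#' @param seed integer seed (initialization and per-epoch shuffling)
#' @param log_clamp_eps clamp floor for logs
#' @param mode "full" (G + C + D), "no_adversarial" (G + C, lambda3 forced
#'   to 0, D never touched), or "caller_only" (C alone on the low image,
#'   duplicated in place of the generated image)
#' @return a `train_config` list
#' @export
train_config <- function(learning_rate = 3e-4, batch_size = 256, epochs = 5,
                         seed = 1, log_clamp_eps = 1e-7, mode = "full") {
  stopifnot(learning_rate > 0, batch_size >= 1, epochs >= 1,
            mode %in% c("full", "no_adversarial", "caller_only"))
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 log_clamp_eps = log_clamp_eps, mode = mode),
            class = "train_config")
}

adam_init <- function(params) {
  list(m = zero_grads(params), v = zero_grads(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# Stack a list of training examples into batch matrices / label vectors.
batch_tensors <- function(examples) {
  list(low = as_batch_matrix(lapply(examples, `[[`, "low_image")),
       high = as_batch_matrix(lapply(examples, `[[`, "high_image")),
       gt21 = vapply(examples, function(e) e$label$gt21, integer(1)),
       zygosity = vapply(examples, function(e) e$label$zygosity, integer(1)),
       len1 = vapply(examples, function(e) e$label$len1, integer(1)),
       len2 = vapply(examples, function(e) e$label$len2, integer(1)))
}

#' One alternating training step
#'
#' @param batch list of training examples (each list(low_image, high_image,
#'   label)) or a prebuilt batch from `batch_tensors`
#' @param g_params,c_params,d_params network parameters
#' @param weights a [loss_weights()]
#' @param opt_gc,opt_d Adam states (from `adam_init` over the concatenated
#'   G+C parameters, and over D's)
#' @param config a [train_config()]
#' @return list(g_params, c_params, d_params, opt_gc, opt_d, record) where
#'   `record` holds l_g, l_c, l_adver, l_total, l_d for the step
#' @export
train_step <- function(batch, g_params, c_params, d_params, weights,
                       opt_gc, opt_d, config = train_config()) {
  bt <- if (is.list(batch) && !is.null(batch$low)) batch else
    batch_tensors(batch)
  N <- ncol(bt$low) / (IMG_H * IMG_W)
  eps <- config$log_clamp_eps
  caller_only <- config$mode == "caller_only"
  no_adv <- config$mode != "full"
  lam3 <- if (no_adv) 0 else weights$lambda3

  # ---- phase 1: G and C ----
  if (caller_only) {
    gen_out <- bt$low
    gfwd <- NULL
  } else {
    gfwd <- generator_forward(g_params, bt$low, want_cache = TRUE)
    gen_out <- gfwd$out
  }
  l_g <- if (caller_only) 0 else mean((gen_out - bt$high)^2)

  cfwd <- caller_forward(c_params, gen_out, bt$low, want_cache = TRUE)
  fh <- list(
    gt21 = focal_head(cfwd$logits$gt21, bt$gt21, weights$gamma, eps),
    zygosity = focal_head(cfwd$logits$zygosity, bt$zygosity, weights$gamma,
                          eps),
    len1 = focal_head(cfwd$logits$len1, bt$len1, weights$gamma, eps),
    len2 = focal_head(cfwd$logits$len2, bt$len2, weights$gamma, eps))
  l_c <- sum(vapply(fh, `[[`, numeric(1), "loss"))

  if (lam3 > 0) {
    dfwd <- discriminator_forward(d_params, gen_out, bt$low,
                                  want_cache = TRUE)
    l_adver <- adversarial_g_loss(dfwd$out, eps)
  } else {
    dfwd <- NULL
    l_adver <- if (no_adv || caller_only) 0 else {
      adversarial_g_loss(discriminator_forward(d_params, gen_out,
                                               bt$low)$out, eps)
    }
  }
  l_total <- weights$lambda1 * l_g + weights$lambda2 * l_c + lam3 * l_adver
  if (!is.finite(l_total) || (lam3 > 0 && !is.finite(l_adver)))
    stop("non-finite loss in train_step (l_g=", l_g, ", l_c=", l_c,
         ", l_adver=", l_adver, ")")

  cbwd <- caller_backward(c_params, cfwd$cache,
                          lapply(fh, function(h)
                            weights$lambda2 * h$dlogits))
  c_grads <- cbwd$grads

  if (!caller_only) {
    dgen <- weights$lambda1 * 2 * (gen_out - bt$high) / length(gen_out)
    dgen <- dgen + cbwd$dGenerated
    if (lam3 > 0) {
      # d(-mean log d_fake)/d d_fake = -1/(N * d_fake), clamped region flat
      dP <- ifelse(dfwd$out > eps, -1 / (N * dfwd$out), 0) * lam3
      dD <- discriminator_backward(d_params, dfwd$cache, dP)
      dgen <- dgen + dD$dCandidate
    }
    g_grads <- generator_backward(g_params, gfwd$cache, dgen)
    gc_grads <- c(prefix_names(g_grads, "G."), prefix_names(c_grads, "C."))
    gc_params <- c(prefix_names(g_params, "G."), prefix_names(c_params, "C."))
  } else {
    gc_grads <- prefix_names(c_grads, "C.")
    gc_params <- prefix_names(c_params, "C.")
  }
  upd <- adam_step(gc_params, gc_grads, opt_gc, config$learning_rate)
  opt_gc <- upd$state
  if (!caller_only) {
    g_params <- strip_names(upd$params, "G.", g_params)
    c_params <- strip_names(upd$params, "C.", c_params)
  } else {
    c_params <- strip_names(upd$params, "C.", c_params)
  }

  # ---- phase 2: D on (high, low) vs (generated detached, low) ----
  # the generated batch of phase 1 is reused detached (the two-player game
  # trains D against the generator state that produced the samples)
  l_d <- NA_real_
  if (config$mode == "full") {
    if (is.null(dfwd))
      dfwd <- discriminator_forward(d_params, gen_out, bt$low,
                                    want_cache = TRUE, slot = 0L)
    dr <- discriminator_forward(d_params, bt$high, bt$low, want_cache = TRUE,
                                slot = 1L)
    l_d <- discriminator_loss(dr$out, dfwd$out, eps)
    if (!is.finite(l_d)) stop("non-finite discriminator loss")
    dPr <- ifelse(dr$out > eps, -1 / (N * dr$out), 0)
    dPf <- ifelse(1 - dfwd$out > eps, 1 / (N * (1 - dfwd$out)), 0)
    gr <- discriminator_backward(d_params, dr$cache, dPr)$grads
    gf <- discriminator_backward(d_params, dfwd$cache, dPf)$grads
    d_grads <- Map(`+`, gr, gf)
    updd <- adam_step(d_params, d_grads, opt_d, config$learning_rate)
    d_params <- updd$params
    class(d_params) <- c("disc_params", "dl_params")
    opt_d <- updd$state
  }

  list(g_params = g_params, c_params = c_params, d_params = d_params,
       opt_gc = opt_gc, opt_d = opt_d,
       record = list(l_g = l_g, l_c = l_c, l_adver = l_adver,
                     l_total = l_total, l_d = l_d))
}

prefix_names <- function(x, pre) stats::setNames(unclass(x),
                                                 paste0(pre, names(x)))

strip_names <- function(x, pre, template) {
  sel <- startsWith(names(x), pre)
  out <- stats::setNames(x[sel], substring(names(x)[sel], nchar(pre) + 1L))
  class(out) <- class(template)
  out
}

#' Fit the model on a dataset
#'
#' Shuffles with the config seed each epoch, runs [train_step()] over
#' mini-batches, and records per-epoch mean losses. With
#' `mode = "no_adversarial"` the discriminator is never updated (the G + C
#' ablation); with `mode = "caller_only"` only C is trained on the low-depth
#' image (the plain-caller baseline).
#'
#' @param dataset list of training examples (from [make_training_pairs()])
#' @param weights a [loss_weights()]
#' @param config a [train_config()]
#' @param checkpoint_dir optional directory for per-epoch checkpoints
#' @param verbose print per-epoch summaries?
#' @return list(g_params, c_params, d_params, history = data.frame of
#'   per-epoch mean losses, config, weights)
#' @export
fit <- function(dataset, weights = loss_weights(), config = train_config(),
                checkpoint_dir = NULL, verbose = FALSE) {
  stopifnot(length(dataset) >= 1L)
  g_params <- init_generator(config$seed)
  c_params <- init_caller(config$seed)
  d_params <- init_discriminator(config$seed)
  gc0 <- if (config$mode == "caller_only") prefix_names(c_params, "C.") else
    c(prefix_names(g_params, "G."), prefix_names(c_params, "C."))
  opt_gc <- adam_init(gc0)
  opt_d <- adam_init(d_params)
  history <- vector("list", config$epochs)
  n <- length(dataset)
  for (ep in seq_len(config$epochs)) {
    set.seed(derive_seed(config$seed, 100L + ep))
    ord <- sample.int(n)
    recs <- list()
    for (b0 in seq(1L, n, by = config$batch_size)) {
      idx <- ord[b0:min(b0 + config$batch_size - 1L, n)]
      st <- train_step(dataset[idx], g_params, c_params, d_params, weights,
                       opt_gc, opt_d, config)
      g_params <- st$g_params; c_params <- st$c_params
      d_params <- st$d_params
      opt_gc <- st$opt_gc; opt_d <- st$opt_d
      recs[[length(recs) + 1L]] <- st$record
    }
    ep_mean <- function(f) mean(vapply(recs, `[[`, numeric(1), f),
                                na.rm = TRUE)
    history[[ep]] <- data.frame(
      epoch = ep, l_g = ep_mean("l_g"), l_c = ep_mean("l_c"),
      l_adver = ep_mean("l_adver"), l_total = ep_mean("l_total"),
      l_d = ep_mean("l_d"))
    if (verbose)
      log_msg("epoch %d/%d: l_total=%.4f l_g=%.4f l_c=%.4f l_d=%.4f", ep,
              config$epochs, history[[ep]]$l_total, history[[ep]]$l_g,
              history[[ep]]$l_c, history[[ep]]$l_d)
    if (!is.null(checkpoint_dir))
      save_checkpoint(list(g_params = g_params, c_params = c_params,
                           d_params = d_params, epoch = ep,
                           seed = config$seed),
                      file.path(checkpoint_dir, sprintf("epoch%03d.rds", ep)))
  }
  list(g_params = g_params, c_params = c_params, d_params = d_params,
       history = do.call(rbind, history), config = config, weights = weights)
}

#' Save / load a parameter checkpoint
#'
#' A single-file archive with a JSON sidecar header (epoch, seed).
#'
#' @param obj list of parameters and metadata
#' @param path destination (.rds)
#' @return `path`, invisibly
#' @export
save_checkpoint <- function(obj, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  saveRDS(obj, path)
  meta <- list(epoch = obj$epoch, seed = obj$seed,
               saved = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)
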