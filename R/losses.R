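# Loss functions. Natural logarithms throughout; probabilities entering a
# log are clamped at `eps` (default 1e-7); batch reduction is the mean.

#' Focal loss
#'
#' `-(1 - p_t)^gamma * log(p_t)` with `p_t` the probability assigned to the
#' true class, clamped to `[eps, 1]`. With `gamma = 0` this is cross-entropy.
#' Vector inputs are reduced by the mean.
#'
#' @param probs probability vector (one distribution) or matrix (K x N)
#' @param target 0-based class index (scalar or length-N vector)
#' @param gamma focusing parameter (default 2)
#' @param eps clamp floor for the log
#' @return non-negative scalar
#' @export
focal_loss <- function(probs, target, gamma = 2, eps = 1e-7) {
  if (is.matrix(probs)) {
    stopifnot(length(target) == ncol(probs))
    stopifnot(all(target >= 0L), all(target < nrow(probs)))
    pt <- probs[cbind(as.integer(target) + 1L, seq_len(ncol(probs)))]
  } else {
    stopifnot(length(target) == 1L, target >= 0L, target < length(probs))
    pt <- probs[as.integer(target) + 1L]
  }
  pt <- pmin(pmax(pt, eps), 1)
  mean(-(1 - pt)^gamma * log(pt))
}

#' Multi-task caller loss
#'
#' Sum of the focal losses of the four attribute heads (genotype, zygosity,
#' and the two allele length changes), each task weighted equally.
#'
#' @param pred list with probability vectors/matrices gt21, zygosity, len1,
#'   len2 (as returned in `caller_forward()$probs`)
#' @param label list with 0-based indices gt21, zygosity, len1, len2 (scalars
#'   or length-N vectors)
#' @param gamma focusing parameter
#' @return non-negative scalar
#' @export
caller_loss <- function(pred, label, gamma = 2) {
  focal_loss(pred$gt21, label$gt21, gamma) +
    focal_loss(pred$zygosity, label$zygosity, gamma) +
    focal_loss(pred$len1, label$len1, gamma) +
    focal_loss(pred$len2, label$len2, gamma)
}

#' Generator reconstruction loss (mean squared error)
#'
#' Mean over batch and pixels of the squared difference between the
#' generated and the observed high-depth image.
#'
#' @param generated,target image batches: matrices of equal dimension or
#'   lists of 33 x 32 matrices
#' @return non-negative scalar; 0 iff the batches are identical
#' @export
generator_loss <- function(generated, target) {
  G <- if (is.list(generated)) as_batch_matrix(generated) else generated
  Tg <- if (is.list(target)) as_batch_matrix(target) else target
  stopifnot(length(G) == length(Tg))
  mean((G - Tg)^2)
}

#' Adversarial loss for the generator
#'
#' `-mean(log D(G(I), I))`: low when the discriminator is fooled.
#'
#' @param d_fake discriminator probabilities on generated images
#' @param eps clamp floor
#' @return non-negative scalar
#' @export
adversarial_g_loss <- function(d_fake, eps = 1e-7) {
  mean(-log(pmax(d_fake, eps)))
}

#' Discriminator loss
#'
#' `-mean(log D(I_gt, I) + log(1 - D(G(I), I)))`.
#'
#' @param d_real probabilities on observed high-depth images
#' @param d_fake probabilities on generated images
#' @param eps clamp floor
#' @return non-negative scalar
#' @export
discriminator_loss <- function(d_real, d_fake, eps = 1e-7) {
  mean(-(log(pmax(d_real, eps)) + log(pmax(1 - d_fake, eps))))
}

#' Loss weights of the joint objective
#'
#' The generator/caller phase minimizes
#' `lambda1 * L_G + lambda2 * L_C + lambda3 * L_adver`.
#'
#' @param lambda1,lambda2 weights of the reconstruction and caller losses
#'   (default 1)
#' @param lambda3 weight of the adversarial term (default 0.1)
#' @param gamma focal-loss focusing parameter (default 2)
#' @return a `loss_weights` list
#' @export
loss_weights <- function(lambda1 = 1, lambda2 = 1, lambda3 = 0.1,
                         gamma = 2) {
  stopifnot(lambda1 >= 0, lambda2 >= 0, lambda3 >= 0, gamma >= 0)
  structure(list(lambda1 = lambda1, lambda2 = lambda2, lambda3 = lambda3,
                 gamma = gamma), class = "loss_weights")
}
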