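# FGSM adversarial layer: single-step perturbation of document embeddings
# along the sign of the input gradient, dual-loss defended training, and
# attacked-vs-clean evaluation.

#' FGSM perturbation settings
#'
#' @param epsilon L-infinity magnitude of the perturbation (default 0.05,
#'   the standard setting used throughout).
#' @param lambda_weight Weight of the adversarial loss term in
#'   `L = L_org + lambda * L_adv` (default 1).
#' @return A `feba_perturbation`.
#' @export
perturbation <- function(epsilon = 0.05, lambda_weight = 1.0) {
  stopifnot(epsilon >= 0, lambda_weight >= 0)
  structure(list(epsilon = epsilon, lambda_weight = lambda_weight),
            class = "feba_perturbation")
}

#' @export
print.feba_perturbation <- function(x, ...) {
  cat(sprintf("<feba_perturbation> epsilon = %g, lambda = %g\n",
              x$epsilon, x$lambda_weight))
  invisible(x)
}

#' Fast gradient sign perturbation
#'
#' `perturbed = x + epsilon * sign(g)`, with `sign(0) = 0` so zero-gradient
#' coordinates are left untouched. The result deviates from `x` by at most
#' `epsilon` per coordinate.
#'
#' @param x Numeric embedding batch (matrix or vector).
#' @param g Gradient field of the loss with respect to `x`, same shape.
#' @param p A [perturbation()].
#' @return Perturbed batch, same shape as `x`.
#' @export
fgsm_perturb <- function(x, g, p = perturbation()) {
  stopifnot(inherits(p, "feba_perturbation"))
  if (!identical(dim(x), dim(g)) || length(x) != length(g)) {
    stop_feba("x and g shapes differ")
  }
  if (!all(is.finite(g))) stop_feba("gradient field has non-finite entries")
  x + p$epsilon * sign(g)
}

#' Assemble an adversarial batch
#'
#' Bundles the original embeddings, the gradient field, the FGSM-perturbed
#' embeddings, and the literal original-plus-adversarial combination
#' `combined = original + perturbed` retained for fidelity with the additive
#' formulation (defended training itself uses the dual loss, see
#' [adversarial_train()]).
#'
#' @inheritParams fgsm_perturb
#' @return A `feba_adv_batch` with `original`, `gradient`, `perturbed`,
#'   `combined`, `epsilon`.
#' @export
adversarial_batch <- function(x, g, p = perturbation()) {
  pert <- fgsm_perturb(x, g, p)
  structure(list(original = x, gradient = g, perturbed = pert,
                 combined = x + pert, epsilon = p$epsilon),
            class = "feba_adv_batch")
}

#' Dual training loss
#'
#' `L = L_org + lambda * L_adv`.
#'
#' @param loss_org Loss on the original examples (>= 0).
#' @param loss_adv Loss on the adversarial examples (>= 0).
#' @param p A [perturbation()] supplying `lambda_weight`.
#' @return The combined loss.
#' @export
combined_loss <- function(loss_org, loss_adv, p = perturbation()) {
  stopifnot(loss_org >= 0, loss_adv >= 0, inherits(p, "feba_perturbation"))
  loss_org + p$lambda_weight * loss_adv
}

#' Train a defended (adversarially trained) ensemble
#'
#' Identical to [train_ensemble()] except every weak-learner fit descends
#' the dual objective: each epoch regenerates FGSM examples at the current
#' parameters and combines their loss with the clean loss as
#' `L_org + lambda * L_adv`. With `epsilon = 0` the defended trajectory
#' coincides exactly with undefended training.
#'
#' @inheritParams train_ensemble
#' @param p A [perturbation()].
#' @return A defended `feba_ensemble`.
#' @export
adversarial_train <- function(train, val, specs, threshold = 0.5,
                              p = perturbation(), vote = "accuracy") {
  train_ensemble(train, val, specs, threshold = threshold,
                 adversarial = p, vote = vote)
}

# Vote-weighted average of per-learner input gradients: the gradient field
# of the ensemble's averaged loss, used to attack the ensemble as a whole.
ensemble_input_gradient <- function(ens, X, y) {
  stopifnot(inherits(ens, "feba_ensemble"))
  vw <- ens$vote_weights / sum(ens$vote_weights)
  G <- 0
  for (k in seq_along(ens$learners)) {
    G <- G + vw[k] * input_gradient(ens$learners[[k]], X, y)
  }
  G
}

confidence_histogram <- function(conf, breaks = seq(0.5, 1, by = 0.05)) {
  conf <- pmin(pmax(conf, 0.5), 1)
  counts <- table(cut(conf, breaks, include.lowest = TRUE))
  data.frame(bin_low = breaks[-length(breaks)],
             bin_high = breaks[-1],
             count = as.integer(counts))
}

#' Evaluate an ensemble under FGSM attack
#'
#' Computes clean metrics on `X` and attacked metrics on
#' `fgsm_perturb(X, g, p)` where `g` is the gradient field of the
#' ensemble's vote-weight-averaged loss at the true labels. Confidence
#' distributions (vote-share histograms) are returned for both conditions.
#'
#' @param ens A `feba_ensemble`.
#' @param X Numeric matrix or labeled `feba_dem`.
#' @param y True 0/1 labels (taken from `X` when it is a labeled `feba_dem`).
#' @param p A [perturbation()].
#' @return A `feba_attack_report`: `clean` and `attacked` metric blocks
#'   (see [confusion_and_metrics()]), `confidence` histograms, `epsilon`.
#' @export
attack_evaluate <- function(ens, X, y = NULL, p = perturbation()) {
  if (inherits(X, "feba_dem")) {
    y <- y %||% X$labels
    X <- X$X
  }
  X <- as.matrix(X)
  if (is.null(y)) stop_feba("true labels required")
  clean <- predict_vote(ens, X)
  g <- ensemble_input_gradient(ens, X, y)
  X_adv <- fgsm_perturb(X, g, p)
  adv <- predict_vote(ens, X_adv)
  structure(list(
    clean = confusion_and_metrics(y, clean$labels),
    attacked = confusion_and_metrics(y, adv$labels),
    confidence = list(clean = confidence_histogram(clean$confidence),
                      attacked = confidence_histogram(adv$confidence)),
    epsilon = p$epsilon, lambda_weight = p$lambda_weight),
    class = "feba_attack_report")
}

#' @export
print.feba_attack_report <- function(x, ...) {
  cat(sprintf("<feba_attack_report> eps = %g: clean accuracy %.3f, attacked accuracy %.3f\n",
              x$epsilon, x$clean$accuracy, x$attacked$accuracy))
  invisible(x)
}

#' Two-dimensional seeded projection for decision-boundary plots
#'
#' Projects an embedding matrix onto two seeded random orthonormal
#' directions; a light-weight stand-in for rendering decision regions in
#' the plane.
#'
#' @param X Numeric matrix.
#' @param seed Seed for the projection.
#' @return n x 2 matrix.
#' @export
project_2d <- function(X, seed = 1L) {
  X <- as.matrix(X)
  d <- ncol(X)
  B <- with_seed(seed, matrix(rnorm(d * 2), d, 2))
  B <- qr.Q(qr(B))
  X %*% B
}
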