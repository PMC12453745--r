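# The boosting core: sequential weak-learner training with additive
# re-weighting of misclassified samples, validation-threshold gating, and
# weighted majority voting.
#
# The loop reads: normalize the sample weights to mean 1, fit the next
# learner under the weighted loss, measure validation accuracy; if it beats
# the acceptance threshold, accept the learner with vote weight equal to its
# validation accuracy and add +1 to the weight of every *training* sample it
# misclassified, so the next learner prioritizes them. Misclassification
# indices address training rows (the weights being updated are training
# weights); validation accuracy only gates acceptance and sets the vote
# weight.

#' Initialize boosting sample weights
#'
#' All samples start at weight 1 (equal weights).
#'
#' @param n Number of training samples (>= 1).
#' @return Numeric n-vector of ones.
#' @export
init_weights <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop_feba("n must be a positive integer")
  }
  rep(1, as.integer(n))
}

#' Additively re-weight misclassified samples
#'
#' `w_i <- w_i + 1` for every index in `misclassified`; all other weights
#' are unchanged. Applying updates repeatedly accumulates, so weights are
#' non-decreasing over the boosting loop.
#'
#' @param w Numeric weight vector (entries >= 1).
#' @param misclassified Integer indices into `w` (possibly empty).
#' @return Updated weight vector.
#' @examples
#' update_weights(c(1, 1, 1, 1), c(2, 4))
#' @export
update_weights <- function(w, misclassified) {
  misclassified <- as.integer(misclassified)
  if (length(misclassified) &&
      (min(misclassified) < 1L || max(misclassified) > length(w))) {
    stop_feba("misclassified index out of range")
  }
  w[misclassified] <- w[misclassified] + 1
  w
}

#' Train a boosted ensemble of weak learners
#'
#' @param train A labeled `feba_dem` (training split).
#' @param val A labeled `feba_dem` (validation split, same feature space).
#' @param specs List of [weak_learner_spec()] (e.g. [learner_roster()]).
#' @param threshold Validation-accuracy acceptance gate (default 0.5, better
#'   than chance). A learner is accepted only if its validation accuracy is
#'   strictly greater.
#' @param adversarial Optional [perturbation()]: defended training (every
#'   learner fits the dual loss `L_org + lambda * L_adv` on fresh FGSM
#'   examples each epoch).
#' @param vote Vote-weight rule: `"accuracy"` (validation accuracy, default)
#'   or `"log_odds"` (AdaBoost-style `0.5 * log(a / (1 - a))`, offered for
#'   comparison; departs the (0, 1] range).
#' @return A `feba_ensemble`: accepted `learners`, `vote_weights`,
#'   `final_weights` (training sample-weight snapshot), `threshold`, and a
#'   per-learner `history` (accepted or not).
#' @export
train_ensemble <- function(train, val, specs, threshold = 0.5,
                           adversarial = NULL,
                           vote = c("accuracy", "log_odds")) {
  vote <- match.arg(vote)
  stopifnot(inherits(train, "feba_dem"), inherits(val, "feba_dem"),
            length(specs) >= 1L)
  if (is.null(train$labels) || is.null(val$labels)) {
    stop_feba("train and val must be labeled")
  }
  if (ncol(train$X) != ncol(val$X)) {
    stop_feba("train and val feature dimensions differ")
  }
  ytr <- train$labels
  yva <- val$labels
  n <- nrow(train$X)
  w <- init_weights(n)
  learners <- list()
  vote_weights <- numeric(0)
  history <- data.frame(index = integer(0), kind = character(0),
                        val_accuracy = numeric(0), n_misclassified = integer(0),
                        accepted = logical(0))
  for (k in seq_along(specs)) {
    wn <- w / mean(w)                       # scale-stable weighted loss
    model <- fit_weak_learner(specs[[k]], train$X, ytr, wn,
                              adversarial = adversarial)
    val_acc <- mean(as.integer(predict_weak(model, val$X) >= 0.5) == yva)
    mis <- which(as.integer(predict_weak(model, train$X) >= 0.5) != ytr)
    accepted <- val_acc > threshold
    history <- rbind(history, data.frame(index = k, kind = specs[[k]]$kind,
                                         val_accuracy = val_acc,
                                         n_misclassified = length(mis),
                                         accepted = accepted))
    if (accepted) {
      learners[[length(learners) + 1L]] <- model
      vw <- if (vote == "accuracy") val_acc else
        0.5 * log(pmin(val_acc, 1 - 1e-6) / pmax(1 - val_acc, 1e-6))
      vote_weights <- c(vote_weights, vw)
      w <- update_weights(w, mis)
    }
  }
  if (!length(learners)) {
    stop_feba("empty ensemble: no learner exceeded threshold %.3f (best validation accuracy %.3f)",
              threshold, max(history$val_accuracy))
  }
  structure(list(learners = learners, vote_weights = vote_weights,
                 final_weights = w, threshold = threshold,
                 history = history, adversarial = adversarial,
                 vote = vote),
            class = "feba_ensemble")
}

#' @export
print.feba_ensemble <- function(x, ...) {
  cat(sprintf("<feba_ensemble> %d/%d learners accepted (threshold %.2f)%s\n",
              length(x$learners), nrow(x$history), x$threshold,
              if (!is.null(x$adversarial))
                sprintf("; defended (eps = %g, lambda = %g)",
                        x$adversarial$epsilon, x$adversarial$lambda_weight)
              else ""))
  cat(sprintf("  vote weights: %s\n",
              paste(sprintf("%.3f", x$vote_weights), collapse = ", ")))
  invisible(x)
}

#' Weighted majority vote from a prediction matrix
#'
#' Per sample, each class accumulates the vote weights of the learners
#' predicting it; the heavier class wins and the winning share is the
#' confidence. An exact tie resolves to label 0.
#'
#' @param preds n x L matrix of 0/1 predictions (one column per learner).
#' @param vote_weights Positive per-learner vote weights (length L).
#' @return List with `labels` (0/1), `confidence` (in \[0.5, 1\] for
#'   positive weights) and `score` (weighted vote share of class 1, a
#'   continuous ranking score).
#' @export
vote_from_predictions <- function(preds, vote_weights) {
  preds <- as.matrix(preds)
  stopifnot(ncol(preds) == length(vote_weights), all(preds %in% c(0, 1)))
  s1 <- as.numeric(preds %*% vote_weights)
  total <- sum(vote_weights)
  s0 <- total - s1
  labels <- as.integer(s1 > s0)             # tie -> 0
  list(labels = labels,
       confidence = pmax(s0, s1) / total,
       score = s1 / total)
}

#' Predict with a boosted ensemble
#'
#' @param ens A `feba_ensemble`.
#' @param X Numeric matrix or `feba_dem` in the ensemble's feature space.
#' @return As [vote_from_predictions()].
#' @export
predict_vote <- function(ens, X) {
  stopifnot(inherits(ens, "feba_ensemble"))
  if (inherits(X, "feba_dem")) X <- X$X
  if (!length(ens$learners)) stop_feba("empty ensemble")
  preds <- vapply(ens$learners,
                  function(m) as.integer(predict_weak(m, X) >= 0.5),
                  integer(nrow(X)))
  preds <- matrix(preds, nrow = nrow(X))
  vote_from_predictions(preds, ens$vote_weights)
}
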