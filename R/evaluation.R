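#' Classification metrics from a confusion table
#'
#' False/true positive rate, specificity, precision, sensitivity, accuracy
#' and F1 from counts of true positives, true negatives, false positives and
#' false negatives.  A metric whose denominator is zero is reported as
#' \code{NA} (undefined), never as 0.
#'
#' @param tp,tn,fp,fn nonnegative integer counts.
#' @return Named numeric vector with elements \code{FPR}, \code{TPR},
#'   \code{Spe}, \code{Pre}, \code{Sen}, \code{Acc}, \code{F1}.
#' @examples
#' compute_metrics(tp = 3, tn = 5, fp = 1, fn = 1)
#' @export
compute_metrics <- function(tp, tn, fp, fn) {
  counts <- c(tp, tn, fp, fn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("confusion counts must be nonnegative integers")
  sdiv <- function(a, b) if (b == 0) NA_real_ else a / b
  pre <- sdiv(tp, tp + fp)
  sen <- sdiv(tp, tp + fn)
  f1 <- if (is.na(pre) || is.na(sen) || pre + sen == 0) NA_real_ else
    2 * pre * sen / (pre + sen)
  c(FPR = sdiv(fp, tn + fp),
    TPR = sen,
    Spe = sdiv(tn, tn + fp),
    Pre = pre,
    Sen = sen,
    Acc = sdiv(tp + tn, tp + tn + fp + fn),
    F1 = f1)
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney rank statistic: the probability that a
#' randomly chosen positive outscores a randomly chosen negative, with ties
#' counting one half.  1 is perfect ranking, 0.5 is chance.
#'
#' @param scores numeric prediction scores.
#' @param labels logical (or 0/1) class labels, \code{TRUE} = positive.
#' @return AUC in [0, 1].
#' @export
auc_score <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) stop("scores and labels differ in length")
  np <- sum(labels)
  nn <- sum(!labels)
  if (np == 0 || nn == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[labels]) - np * (np + 1) / 2) / (np * nn)
}

assign_folds <- function(n_pos, k) {
  # seeded shuffle; remainder spread one per fold
  fold <- rep(seq_len(k), length.out = n_pos)
  sample(fold)
}

#' k-fold cross-validation of the predictor
#'
#' Splits the known interactions into k folds.  For each fold the test
#' positives are zeroed out of the training network, the bilayer is rebuilt
#' with the similarity layers, the perturbation predictor is fitted
#' (\code{\link{spmc}}), and the held-out positives are scored against an
#' equal-sized (or \code{neg_ratio}-sized) sample of never-observed pairs.
#' AUC is threshold-free; the thresholded metrics use a score cutoff at the
#' median of the evaluated pair scores (a balanced decision point).
#'
#' @param lm an \code{\link{interaction_network}} with all known
#'   interactions.
#' @param sl,sm similarity layers, or \code{NULL} for ablations.
#' @param k number of folds.
#' @param t,fraction predictor settings, see \code{\link{spmc}}.
#' @param neg_ratio negatives sampled per test positive.
#' @param seed master seed governing fold assignment, negative sampling and
#'   the predictor's perturbations.
#' @return Object of class \code{"spmc_cv"}: \code{folds} data.frame of
#'   per-fold AUC and metrics, \code{mean} and \code{sd} rows, the fold
#'   \code{assignments}, and the settings.
#' @examples
#' sim <- simulate_lmi(m = 30, n = 15, seed = 3)
#' cv <- cross_validate(sim$lm, sim$sl, sim$sm, k = 3, t = 2, seed = 1)
#' cv
#' @export
cross_validate <- function(lm, sl = NULL, sm = NULL, k = 5, t = 16,
                           fraction = 0.1, neg_ratio = 1, seed = NULL) {
  stopifnot(inherits(lm, "lmi_network"))
  pos <- which(lm$lm == 1)
  if (length(pos) < k) stop("fewer known interactions than folds")
  if (!is.null(seed)) set.seed(seed)
  folds <- assign_folds(length(pos), k)
  fold_seeds <- derive_seeds(if (is.null(seed)) NULL else seed + 1L, 2L * k)
  zeros_all <- which(lm$lm == 0)
  per_fold <- vector("list", k)
  for (f in seq_len(k)) {
    test_pos <- pos[folds == f]
    train_adj <- lm$lm
    train_adj[test_pos] <- 0
    train_net <- interaction_network(train_adj, lm$lnc_ids, lm$mi_ids)
    fit <- spmc(train_net, sl, sm, t = t, fraction = fraction,
                seed = fold_seeds[[2L * f - 1L]], pool = "all")
    n_neg <- min(round(neg_ratio * length(test_pos)), length(zeros_all))
    if (n_neg < 1) stop("no negatives available")
    if (!is.null(seed)) set.seed(fold_seeds[[2L * f]])
    test_neg <- sample(zeros_all, n_neg)
    sc <- c(fit$scores[test_pos], fit$scores[test_neg])
    lab <- c(rep(TRUE, length(test_pos)), rep(FALSE, n_neg))
    thr <- stats::median(sc)
    pred_pos <- sc > thr
    met <- compute_metrics(tp = sum(pred_pos & lab), tn = sum(!pred_pos & !lab),
                           fp = sum(pred_pos & !lab), fn = sum(!pred_pos & lab))
    per_fold[[f]] <- c(AUC = auc_score(sc, lab), met)
  }
  folds_df <- as.data.frame(do.call(rbind, per_fold))
  folds_df <- cbind(fold = seq_len(k), folds_df)
  structure(
    list(folds = folds_df,
         mean = colMeans(folds_df[-1], na.rm = TRUE),
         sd = apply(folds_df[-1], 2, stats::sd, na.rm = TRUE),
         assignments = folds, k = k, t = t, fraction = fraction,
         neg_ratio = neg_ratio, seed = seed),
    class = "spmc_cv")
}

#' @export
print.spmc_cv <- function(x, digits = 4, ...) {
  cat(x$k, "-fold cross-validation (t = ", x$t, ", fraction = ",
      x$fraction, ")\n", sep = "")
  print(round(x$folds, digits))
  cat(sprintf("mean AUC %.4f +/- %.4f\n", x$mean["AUC"], x$sd["AUC"]))
  invisible(x)
}

#' @method summary spmc_cv
#' @export
summary.spmc_cv <- function(object, ...) {
  data.frame(metric = names(object$mean),
             mean = unname(object$mean),
             sd = unname(object$sd))
}
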