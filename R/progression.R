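#' First-to-last eGFR slope
#'
#' slope = (eGFR_last - eGFR_first) / (t_last - t_first); intermediate
#' measurements are ignored by definition.
#'
#' @param time numeric times in years, strictly increasing, length >= 2.
#' @param egfr eGFR at each time.
#' @return slope in mL/min/1.73 m^2 per year.
#' @export
egfr_slope <- function(time, egfr) {
  if (length(time) < 2) stop("need >= 2 time points")
  if (length(time) != length(egfr)) stop("time and egfr lengths differ")
  if (any(diff(time) <= 0)) stop("times must be strictly increasing")
  (egfr[length(egfr)] - egfr[1]) / (time[length(time)] - time[1])
}

#' Classify eGFR decline from the slope
#'
#' `none` when slope >= -1; `slow` when -3 < slope < -1; `steep` when
#' slope <= -3 (the boundary -3 is assigned to steep).
#'
#' @param slope finite numeric slope(s).
#' @return character vector "none"/"slow"/"steep".
#' @export
classify_decline <- function(slope) {
  if (any(!is.finite(slope))) stop("non-finite slope")
  ifelse(slope >= -1, "none", ifelse(slope > -3, "slow", "steep"))
}

#' Albuminuria progression flag
#'
#' Progressor when the last albuminuria stage strictly exceeds the baseline
#' stage on the ordered scale Normo < Micro < Macro < ESRD; regression to a
#' lower stage counts as nonprogressor.
#'
#' @param baseline,last stage labels.
#' @return logical vector.
#' @export
classify_albuminuria_progression <- function(baseline, last) {
  stages <- c("Normo", "Micro", "Macro", "ESRD")
  if (!all(c(baseline, last) %in% stages)) stop("unknown stage label")
  match(last, stages) > match(baseline, stages)
}

#' Logistic regression by IRLS on standardized features
#'
#' Maximum-likelihood logistic regression fitted by iteratively reweighted
#' least squares. Features are standardized internally (constant columns
#' dropped); convergence when the largest coefficient change falls below
#' `tol`. Perfect separation (diverging coefficients) aborts with a
#' diagnostic.
#'
#' @param x feature matrix (subjects x features); may have 0 columns for an
#'   intercept-only model.
#' @param y binary outcome (0/1), not constant.
#' @param max_iter,tol IRLS controls.
#' @return list of class `logit_fit`: `coefficients` (on the standardized
#'   scale, intercept first), `fitted` (probabilities), `center`, `scale`,
#'   `converged`, `iterations`.
#' @export
fit_logistic <- function(x, y, max_iter = 100, tol = 1e-8) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  if (length(unique(y)) < 2) stop("constant outcome")
  if (!all(y %in% c(0, 1))) stop("outcome must be binary 0/1")
  ctr <- if (ncol(x)) colMeans(x) else numeric(0)
  scl <- if (ncol(x)) apply(x, 2, stats::sd) else numeric(0)
  keep <- scl > 0
  xs <- if (any(keep))
    sweep(sweep(x[, keep, drop = FALSE], 2, ctr[keep]), 2, scl[keep], "/")
  else matrix(nrow = length(y), ncol = 0)
  X <- cbind(intercept = 1, xs)
  beta <- numeric(ncol(X))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    wt <- pmax(p * (1 - p), 1e-10)
    z <- eta + (y - p) / wt
    fit <- stats::lm.wfit(X, z, wt)
    new_beta <- fit$coefficients
    if (anyNA(new_beta)) stop("singular feature matrix")
    delta <- max(abs(new_beta - beta))
    beta <- new_beta
    # on standardized features a coefficient this large only arises when the
    # likelihood is unbounded (separated classes)
    if (max(abs(beta)) > 30)
      stop("perfect separation detected (diverging coefficients)")
    if (delta < tol) { converged <- TRUE; break }
  }
  structure(list(coefficients = beta, fitted = stats::plogis(drop(X %*% beta)),
                 center = ctr, scale = scl, kept = keep,
                 converged = converged, iterations = it),
            class = "logit_fit")
}

#' @export
predict.logit_fit <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  keep <- object$kept
  xs <- if (any(keep))
    sweep(sweep(x[, keep, drop = FALSE], 2, object$center[keep]),
          2, object$scale[keep], "/")
  else matrix(nrow = nrow(x), ncol = 0)
  stats::plogis(drop(cbind(1, xs) %*% object$coefficients))
}

#' Area under the ROC curve
#'
#' AUC via the Mann-Whitney U relation with midrank ties: the probability
#' that a random positive outscores a random negative, ties counting 1/2.
#'
#' @param scores numeric risk scores.
#' @param labels binary outcome (0/1 or logical).
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.numeric(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Bootstrap test of the AUC gain from added features
#'
#' Fits the nested (clinical) and full (clinical + index) logistic models,
#' reports the observed delta-AUC, and bootstraps subjects with replacement,
#' refitting both models per resample. Two-sided fraction-based p-value:
#' twice the proportion of resamples with delta-AUC <= 0, clipped to
#' [2/B, 1]. Resamples with a single outcome class are redrawn (bounded
#' retries).
#'
#' @param features data.frame/matrix of all candidate features.
#' @param nested character vector of nested-model feature names (strict
#'   subset of `colnames(features)`).
#' @param outcome binary outcome.
#' @param B bootstrap replicates, >= 200.
#' @param seed integer seed.
#' @return list with `auc_full`, `auc_nested`, `delta_auc`, `p`,
#'   `boot_delta` (vector of length B).
#' @export
bootstrap_delta_auc <- function(features, nested, outcome, B = 500, seed = 1) {
  features <- as.data.frame(features)
  if (!all(nested %in% colnames(features)))
    stop("nested features must be a subset of the full feature set")
  if (B < 200) stop("B must be >= 200")
  full_x <- as.matrix(features)
  nest_x <- as.matrix(features[, nested, drop = FALSE])
  y <- as.numeric(outcome)

  auc_of <- function(xf, xn, yy) {
    c(roc_auc(fit_logistic(xf, yy)$fitted, yy),
      roc_auc(fit_logistic(xn, yy)$fitted, yy))
  }
  obs <- auc_of(full_x, nest_x, y)
  delta <- obs[1] - obs[2]

  set.seed(seed)
  boot <- numeric(B)
  for (b in seq_len(B)) {
    for (try in 1:50) {
      ix <- sample.int(length(y), replace = TRUE)
      if (length(unique(y[ix])) == 2) break
      if (try == 50) stop("could not draw a resample with both classes")
    }
    ab <- auc_of(full_x[ix, , drop = FALSE], nest_x[ix, , drop = FALSE], y[ix])
    boot[b] <- ab[1] - ab[2]
  }
  p <- min(1, max(2 / B, 2 * mean(boot <= 0)))
  list(auc_full = obs[1], auc_nested = obs[2], delta_auc = delta, p = p,
       boot_delta = boot)
}
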