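#' Fit a multi-output random forest on drug-target expression
#'
#' Learns every circuit's activity simultaneously from the unit-scaled
#' expression of known drug targets (KDTs). The ensemble is a bagged
#' forest of regression trees (one forest per output): trees are grown on
#' row subsamples with per-node feature subsampling and unit shrinkage in
#' a single boosting round, i.e. the random-forest mode of xgboost, which
#' also provides exact TreeSHAP attributions for explanation.
#'
#' @param X sample-by-target feature matrix in `[0, 1]` with column names.
#' @param Y sample-by-circuit response matrix (row-matched to `X`).
#' @param n_trees trees per output forest (default 100).
#' @param max_depth maximum tree depth (default 6).
#' @param seed integer seed; refits with the same seed reproduce
#'   identical predictions.
#' @return object of class `mm_forest` holding one booster per circuit.
#' @export
fit_multioutput_forest <- function(X, Y, n_trees = 100, max_depth = 6,
                                   seed = 1) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  stopifnot(n_trees >= 1)
  if (nrow(X) != nrow(Y)) stop("X and Y sample mismatch")
  if (!is.null(rownames(X)) && !is.null(rownames(Y)) &&
      !identical(rownames(X), rownames(Y)))
    stop("X and Y sample ids differ")
  if (nrow(X) < 10) warning("fewer than 10 samples; fit will be unstable")
  boosters <- vector("list", ncol(Y))
  names(boosters) <- colnames(Y)
  for (j in seq_len(ncol(Y))) {
    params <- list(booster = "gbtree", tree_method = "hist",
                   objective = "reg:squarederror", eta = 1,
                   subsample = 0.632, colsample_bynode = 1 / 3,
                   max_depth = max_depth, lambda = 0, nthread = 1,
                   num_parallel_tree = n_trees,
                   seed = (seed * 2654435761 + j * 7919) %% 2147483647)
    dtr <- xgboost::xgb.DMatrix(X, label = Y[, j], nthread = 1)
    boosters[[j]] <- xgboost::xgb.train(params, dtr, nrounds = 1, verbose = 0)
  }
  structure(list(boosters = boosters, targets = colnames(X),
                 circuits = colnames(Y), n_trees = n_trees,
                 max_depth = max_depth, seed = seed), class = "mm_forest")
}

#' @export
print.mm_forest <- function(x, ...) {
  cat(sprintf("<mm_forest> %d circuits x %d targets, %d trees each\n",
              length(x$circuits), length(x$targets), x$n_trees))
  invisible(x)
}

#' Predict circuit activities from a fitted forest
#'
#' @param object an `mm_forest`.
#' @param newdata sample-by-target matrix.
#' @param ... unused.
#' @return sample-by-circuit prediction matrix.
#' @export
predict.mm_forest <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)[, object$targets, drop = FALSE]
  out <- vapply(object$boosters, function(b)
    stats::predict(b, xgboost::xgb.DMatrix(newdata, nthread = 1)),
    numeric(nrow(newdata)))
  if (nrow(newdata) == 1) out <- matrix(out, nrow = 1,
                                        dimnames = list(NULL, object$circuits))
  rownames(out) <- rownames(newdata)
  out
}

#' Signed Shapley relevance of targets for one circuit
#'
#' Per-sample Shapley attributions are computed with the exact tree-path
#' algorithm (TreeSHAP); they satisfy local accuracy (attributions plus
#' baseline reproduce the prediction). The per-target relevance is the
#' mean absolute attribution signed by the direction of the summed
#' attributions: `sign(sum(phi)) * mean(|phi|)`, so magnitude measures
#' importance and sign the dominant direction of influence.
#'
#' @param model an `mm_forest`.
#' @param X_eval non-empty sample-by-target evaluation matrix.
#' @param circuit circuit id among the model outputs.
#' @return named numeric vector of signed relevances over targets.
#' @export
shap_relevance <- function(model, X_eval, circuit) {
  if (!circuit %in% model$circuits) stop("unknown circuit: ", circuit)
  X_eval <- as.matrix(X_eval)[, model$targets, drop = FALSE]
  stopifnot(nrow(X_eval) >= 1)
  phi <- shap_values(model, X_eval, circuit)
  stats::setNames(sign(colSums(phi)) * colMeans(abs(phi)), model$targets)
}

#' Raw Shapley attribution matrix for one circuit
#'
#' @inheritParams shap_relevance
#' @return sample-by-target matrix of attributions `phi`; the model
#'   baseline is attached as attribute `baseline`.
#' @export
shap_values <- function(model, X_eval, circuit) {
  if (!circuit %in% model$circuits) stop("unknown circuit: ", circuit)
  X_eval <- as.matrix(X_eval)[, model$targets, drop = FALSE]
  contrib <- stats::predict(model$boosters[[circuit]],
                            xgboost::xgb.DMatrix(X_eval, nthread = 1),
                            predcontrib = TRUE)
  contrib <- matrix(contrib, nrow = nrow(X_eval))
  phi <- contrib[, seq_along(model$targets), drop = FALSE]
  colnames(phi) <- model$targets
  attr(phi, "baseline") <- contrib[1, ncol(contrib)]
  phi
}

#' Select the top fraction of targets by absolute relevance
#'
#' Keeps the `k = max(1, ceiling(fraction * d))` targets with largest
#' `|relevance|`. Boundary ties are broken deterministically by ascending
#' target id. Zero-relevance targets are never selected, and an all-zero
#' vector yields an empty selection.
#'
#' @param relevance named numeric vector over targets.
#' @param fraction selected fraction in `(0, 1]` (default 0.05).
#' @return named logical vector of the same length.
#' @export
select_top_fraction <- function(relevance, fraction = 0.05) {
  stopifnot(fraction > 0, fraction <= 1)
  d <- length(relevance)
  k <- max(1L, ceiling(fraction * d))
  mag <- abs(relevance)
  sel <- rep(FALSE, d)
  names(sel) <- names(relevance)
  nz <- which(mag > 0)
  if (!length(nz)) return(sel)
  ord <- nz[order(-mag[nz], names(relevance)[nz])]
  sel[ord[seq_len(min(k, length(ord)))]] <- TRUE
  sel
}

#' Nogueira stability of a feature-selection procedure
#'
#' Given the M boolean selection vectors z_1..z_M produced over M
#' resampling repetitions of a selection method on d features, the
#' statistic is
#' \deqn{\Phi = 1 - \frac{\mathrm{mean}_f s^2_f}{(\bar k/d)(1-\bar k/d)}}
#' with per-feature sample variance \eqn{s^2_f = \frac{M}{M-1}\hat
#' p_f(1-\hat p_f)}, selection frequency \eqn{\hat p_f} and mean selected
#' count \eqn{\bar k}. It equals 1 only for identical non-degenerate
#' selections, is near 0 for random selections, and can go negative for
#' anti-correlated ones.
#'
#' @param profile logical matrix, M repetitions (rows) by d features
#'   (columns); `M >= 2`, `d >= 2`.
#' @return the stability value, or `NA` with a warning when all or none
#'   of the features are selected on average (undefined denominator).
#' @export
nogueira_stability <- function(profile) {
  z <- as.matrix(profile) * 1
  m <- nrow(z); d <- ncol(z)
  stopifnot(m >= 2, d >= 2)
  kbar <- mean(rowSums(z))
  denom <- (kbar / d) * (1 - kbar / d)
  if (denom == 0) {
    warning("degenerate selection profile (mean selected count 0 or d)")
    return(NA_real_)
  }
  pf <- colMeans(z)
  s2 <- m / (m - 1) * pf * (1 - pf)
  1 - mean(s2) / denom
}

r_squared <- function(y, pred) {
  sstot <- sum((y - mean(y))^2)
  if (sstot < 1e-12) return(0)
  1 - sum((y - pred)^2) / sstot
}

#' Stability-validated Shapley selection of drug targets
#'
#' The core selection procedure: over `n_splits` seeded random
#' train/test splits, a multi-output forest is fitted on the training
#' samples; per circuit, the held-out R-squared and the signed Shapley
#' relevances on the held-out samples are computed and the top
#' `fraction` of targets by absolute relevance is selected. Across
#' splits the procedure reports, per circuit, the Nogueira stability of
#' the selections, a 95 percent percentile interval of the held-out
#' R-squared, and the across-split mean signed relevance. A target is
#' finally selected for a circuit when it was picked in more than half
#' the splits, the circuit's selection is stable
#' (`stability > stability_min`) and the circuit is predictable
#' (R-squared interval lower bound above `r2_min`).
#'
#' @param X sample-by-target feature matrix (unit-scaled KDT expression).
#' @param Y sample-by-circuit activity matrix.
#' @param n_splits number of resampling repetitions (>= 2; default 50).
#' @param test_frac held-out fraction per split (default 0.2).
#' @param fraction per-circuit selected target fraction (default 0.05).
#' @param stability_min minimum circuit stability (default 0.4, the
#'   empirical lower effect-size bound for a stable selection).
#' @param r2_min minimum lower R-squared bound (default 0).
#' @param consensus minimum across-split selection frequency (default 0.5,
#'   exclusive).
#' @param n_trees,max_depth forest size per split (see
#'   [fit_multioutput_forest()]).
#' @param seed integer seed governing splits and forests.
#' @return object of class `relevance_result`: list with `relevance`
#'   (circuit-by-target signed matrix), `selection` (logical matrix),
#'   `selection_freq`, `r2_ci` (circuit-by-2), `stability` (per circuit),
#'   `n_splits`, `seed`.
#' @export
stability_selection <- function(X, Y, n_splits = 50, test_frac = 0.2,
                                fraction = 0.05, stability_min = 0.4,
                                r2_min = 0, consensus = 0.5, n_trees = 100,
                                max_depth = 6, seed = 1) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (n_splits < 2) stop("stability is undefined for fewer than 2 splits")
  n <- nrow(X); d <- ncol(X); q <- ncol(Y)
  circuits <- colnames(Y); targets <- colnames(X)
  rel <- array(0, dim = c(n_splits, q, d))
  selected <- array(FALSE, dim = c(n_splits, q, d))
  r2 <- matrix(NA_real_, n_splits, q)
  rng <- local({ set.seed(seed)
    lapply(seq_len(n_splits), function(s) sample(n, round(test_frac * n))) })
  for (s in seq_len(n_splits)) {
    test_idx <- rng[[s]]
    fit <- fit_multioutput_forest(X[-test_idx, , drop = FALSE],
                                  Y[-test_idx, , drop = FALSE],
                                  n_trees = n_trees, max_depth = max_depth,
                                  seed = seed + s)
    Xte <- X[test_idx, , drop = FALSE]
    pred <- predict(fit, Xte)
    for (j in seq_len(q)) {
      r2[s, j] <- r_squared(Y[test_idx, j], pred[, j])
      rv <- shap_relevance(fit, Xte, circuits[j])
      rel[s, j, ] <- rv
      selected[s, j, ] <- select_top_fraction(rv, fraction)
    }
    rm(fit)
    gc(verbose = FALSE)   # release native booster memory between splits
  }
  stability <- vapply(seq_len(q), function(j)
    suppressWarnings(nogueira_stability(selected[, j, , drop = TRUE])),
    numeric(1))
  r2_ci <- t(apply(r2, 2, stats::quantile, probs = c(0.025, 0.975),
                   names = FALSE))
  dimnames(r2_ci) <- list(circuits, c("low", "high"))
  relevance <- apply(rel, c(2, 3), mean)
  freq <- apply(selected, c(2, 3), mean)
  dimnames(relevance) <- dimnames(freq) <- list(circuits, targets)
  circuit_ok <- !is.na(stability) & stability > stability_min &
    r2_ci[, "low"] > r2_min
  selection <- freq > consensus & matrix(circuit_ok, q, d)
  structure(list(relevance = relevance, selection = selection,
                 selection_freq = freq, r2_ci = r2_ci,
                 stability = stats::setNames(stability, circuits),
                 n_splits = n_splits, seed = seed),
            class = "relevance_result")
}

#' @export
print.relevance_result <- function(x, ...) {
  cat(sprintf(paste0("<relevance_result> %d circuits x %d targets, ",
                     "%d splits; %d stable circuits, %d selected pairs\n"),
              nrow(x$relevance), ncol(x$relevance), x$n_splits,
              sum(!is.na(x$stability) & x$stability > 0.4),
              sum(x$selection)))
  invisible(x)
}

#' Targets finally selected in at least one circuit
#'
#' @param result a `relevance_result`.
#' @return character vector of target ids.
#' @export
selected_targets <- function(result) {
  colnames(result$selection)[colSums(result$selection) > 0]
}
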