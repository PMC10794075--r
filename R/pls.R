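#' Fit a PLS-1 regression by NIPALS
#'
#' Classical single-response partial least squares: X and y are
#' mean-centered (no variance scaling), then factors are extracted
#' sequentially -- weight vector proportional to `X'y`, scores, X- and
#' y-loadings -- with X and y deflated after each factor. The regression
#' vector for `a` factors is `b_a = W_a (P_a' W_a)^{-1} q_a`, so prediction
#' via `b` reproduces the sequential reconstruction. Extraction halts
#' early, with the factor count truncated accordingly, if the deflated X
#' is numerically exhausted.
#'
#' @param X samples-by-wavenumbers numeric matrix, no missing values.
#' @param y response vector in g/L; must have positive variance.
#' @param n_factors number of factors to extract (within
#'   `min(nrow(X) - 1, ncol(X))`).
#' @return An object of class `pls1_model`: mean vectors, `W`, `P`, `q`,
#'   the per-factor-count coefficient matrix `coefficients` and the
#'   realized `n_factors`.
#' @export
fit_pls1 <- function(X, y, n_factors) {
  X <- as.matrix(X)
  if (!all(is.finite(X)) || !all(is.finite(y))) stop("missing values in X or y")
  if (nrow(X) != length(y)) stop("X rows and y length differ")
  if (stats::var(y) == 0) stop("response y has zero variance")
  amax <- min(nrow(X) - 1L, ncol(X))
  if (n_factors < 1 || n_factors > amax)
    stop(sprintf("n_factors must be in 1..%d", amax))
  xmean <- colMeans(X)
  ymean <- mean(y)
  Xc <- sweep(X, 2, xmean)
  yc <- y - ymean
  p <- ncol(X)
  W <- P <- matrix(0, p, n_factors)
  q <- numeric(n_factors)
  a_used <- 0L
  for (a in seq_len(n_factors)) {
    if (sum(Xc^2) < 1e-12) break
    w <- drop(crossprod(Xc, yc))
    wn <- sqrt(sum(w^2))
    if (wn < 1e-14) break
    w <- w / wn
    tt <- drop(Xc %*% w)
    tq <- sum(tt^2)
    if (tq < 1e-14) break
    P[, a] <- drop(crossprod(Xc, tt)) / tq
    q[a] <- sum(yc * tt) / tq
    W[, a] <- w
    Xc <- Xc - tcrossprod(tt, P[, a])
    yc <- yc - q[a] * tt
    a_used <- a
  }
  if (a_used == 0L) stop("no PLS factor could be extracted")
  W <- W[, seq_len(a_used), drop = FALSE]
  P <- P[, seq_len(a_used), drop = FALSE]
  q <- q[seq_len(a_used)]
  coef <- vapply(seq_len(a_used), function(a) {
    Wa <- W[, seq_len(a), drop = FALSE]
    drop(Wa %*% solve(crossprod(P[, seq_len(a), drop = FALSE], Wa),
                      q[seq_len(a)]))
  }, numeric(p))
  coef <- matrix(coef, nrow = p)
  dimnames(coef) <- list(colnames(X), NULL)
  structure(list(xmean = xmean, ymean = ymean, W = W, P = P, q = q,
                 coefficients = coef, n_factors = a_used),
            class = "pls1_model")
}

#' Predict from a PLS-1 model
#'
#' `yhat = ymean + (X - xmean) b`, using the coefficient vector for the
#' requested factor count.
#'
#' @param object a [fit_pls1()] model.
#' @param newdata samples-by-wavenumbers matrix with the training column
#'   count.
#' @param n_factors factor count to predict with (default: all extracted).
#' @param ... unused.
#' @return Numeric vector of predictions in g/L.
#' @export
predict.pls1_model <- function(object, newdata, n_factors = object$n_factors,
                               ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$xmean))
    stop(sprintf("newdata has %d columns; model was trained on %d",
                 ncol(newdata), length(object$xmean)))
  if (n_factors < 1 || n_factors > object$n_factors)
    stop("n_factors outside the fitted range")
  drop(sweep(newdata, 2, object$xmean) %*%
         object$coefficients[, n_factors]) + object$ymean
}

#' Seeded group assignment for cross-validation
#'
#' Random partition of `n` samples into `n_groups` groups whose sizes
#' differ by at most one (the first `n %% n_groups` groups get the extra
#' sample). Leave-one-out (`n_groups == n`) is deterministic regardless of
#' seed.
#'
#' @param n number of samples.
#' @param n_groups number of groups (2..n).
#' @param seed optional integer seed; the caller's RNG stream is left
#'   untouched.
#' @return Integer vector of group labels in 1..n_groups.
#' @export
make_folds <- function(n, n_groups, seed = NULL) {
  if (n_groups > n) stop("more groups than samples")
  if (n_groups < 2) stop("need at least two groups")
  if (n_groups == n) return(seq_len(n))
  sizes <- rep(n %/% n_groups, n_groups)
  extra <- n %% n_groups
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  with_local_seed(seed, sample(rep.int(seq_len(n_groups), sizes)))
}

#' Grouped cross-validation of a PLS-1 model
#'
#' For each held-out group a model is trained on the remaining samples and
#' the group is predicted with every factor count up to `max_factors`. One
#' global factor count is then chosen by minimum cross-validated RMSE
#' (ties towards fewer factors). Reported RMSE and R-squared are computed
#' on the pooled held-out predictions at that factor count.
#'
#' @param X samples-by-wavenumbers matrix.
#' @param y response vector (g/L).
#' @param n_groups number of CV groups; `n_groups = nrow(X)` is
#'   leave-one-out.
#' @param seed fold-assignment seed (see [make_folds()]).
#' @param max_factors cap on the factor count (default 10).
#' @param folds optional precomputed group labels, overriding
#'   `n_groups`/`seed`; used to share folds across paired comparisons.
#' @return An object of class `pls_cv`: `rmse`, `r2`, `n_factors`,
#'   `groups`, `predictions` (held-out, at the chosen factor count) and
#'   `rmse_by_factor`.
#' @export
cross_validate <- function(X, y, n_groups = 3, seed = NULL, max_factors = 10,
                           folds = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (is.null(folds)) folds <- make_folds(n, n_groups, seed)
  if (length(folds) != n) stop("folds length must match sample count")
  amax <- min(max_factors,
              min(vapply(unique(folds), function(g) sum(folds != g), 0L)) - 1L,
              ncol(X))
  if (amax < 1) stop("not enough samples per training fold")
  pred <- matrix(NA_real_, n, amax)
  for (g in unique(folds)) {
    te <- folds == g
    fit <- fit_pls1(X[!te, , drop = FALSE], y[!te], amax)
    for (a in seq_len(fit$n_factors))
      pred[te, a] <- predict(fit, X[te, , drop = FALSE], n_factors = a)
    if (fit$n_factors < amax)  # exhausted X: later counts equal the last
      for (a in seq.int(fit$n_factors + 1L, amax))
        pred[te, a] <- pred[te, fit$n_factors]
  }
  rmse_a <- apply(pred, 2, rmse, ref = y)
  a_star <- which.min(rmse_a)  # which.min takes the first, i.e. fewer factors
  p_star <- pred[, a_star]
  structure(list(rmse = rmse_a[a_star],
                 r2 = 1 - sum((p_star - y)^2) / sum((y - mean(y))^2),
                 n_factors = as.integer(a_star),
                 groups = folds,
                 predictions = p_star,
                 rmse_by_factor = rmse_a),
            class = "pls_cv")
}

#' @export
print.pls_cv <- function(x, ...) {
  cat(sprintf("<pls_cv> RMSE %.4g g/L, R2 %.4f, %d factor(s), %d groups\n",
              x$rmse, x$r2, x$n_factors, length(unique(x$groups))))
  invisible(x)
}

#' Run a wavenumber-selection experiment
#'
#' Cross-validates PLS-1 for every component under each of its selection
#' patterns (A/B/C), reusing one fold assignment throughout so the
#' patterns are compared on identical splits.
#'
#' @param ds full-grid absorbance [spectral_dataset()].
#' @param reference [concentration_table()] with the components to model.
#' @param selections named list (per component) of named lists of
#'   selections, e.g. the output of [build_selection()] per component.
#' @param mode `"absorbance"` or `"second_derivative"` explanatory
#'   variables.
#' @param region modelling window in cm\eqn{^{-1}}.
#' @param sg an [sg_params()] (derivative mode).
#' @param n_groups,seed,max_factors cross-validation settings, see
#'   [cross_validate()].
#' @return A data.frame with one row per component and selection
#'   (`component`, `selection`, `n_wavenumbers`, `n_factors`, `rmse`,
#'   `r2`); the full `pls_cv` objects are in attribute `"cv"` and the
#'   shared folds in attribute `"folds"`.
#' @export
run_selection_experiment <- function(ds, reference, selections,
                                     mode = c("absorbance",
                                              "second_derivative"),
                                     region = c(900, 1250), sg = sg_params(),
                                     n_groups = 3, seed = NULL,
                                     max_factors = 10) {
  mode <- match.arg(mode)
  stopifnot(inherits(ds, "spectral_dataset"), inherits(reference, "conc_table"))
  Xfull <- prepare_matrix(ds, region, use_derivative =
                            mode == "second_derivative", p = sg)
  wn_axis <- as.numeric(colnames(Xfull))
  folds <- make_folds(nrow(Xfull), n_groups, seed)
  ref <- conc_matrix(reference)
  if (!all(rownames(Xfull) == rownames(ref)))
    stop("dataset and reference table sample ids/order differ")
  rows <- list()
  cvs <- list()
  for (comp in names(selections)) {
    if (!comp %in% colnames(ref))
      stop(sprintf("component '%s' missing from the reference table", comp))
    for (sel_name in names(selections[[comp]])) {
      sel <- selections[[comp]][[sel_name]]
      wn <- if (inherits(sel, "wn_set")) sel$wavenumber else as.numeric(sel)
      if (length(wn) == 0)
        stop(sprintf("empty selection %s for component %s", sel_name, comp))
      cols <- match_wavenumbers(sort(wn), wn_axis)
      cv <- cross_validate(Xfull[, cols, drop = FALSE], ref[, comp],
                           folds = folds, max_factors = max_factors)
      key <- paste(comp, sel_name, sep = ".")
      cvs[[key]] <- cv
      rows[[key]] <- data.frame(component = comp, selection = sel_name,
                                n_wavenumbers = length(wn),
                                n_factors = cv$n_factors,
                                rmse = cv$rmse, r2 = cv$r2)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "cv") <- cvs
  attr(out, "folds") <- folds
  out
}
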