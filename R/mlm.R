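#' Null mixed model with kinship covariance (P3D step)
#'
#' Fits `y = mu + Q gamma + u + e` with `u ~ N(0, sigma_a^2 K)` and
#' `e ~ N(0, sigma_e^2 I)` by REML over the single variance ratio
#' `delta = sigma_e^2 / sigma_a^2`, using an eigendecomposition of `K` so the
#' profiled likelihood is a cheap one-dimensional optimization. Under the
#' P3D scheme ("population parameters previously determined") this null fit
#' is done once and its variance components are reused for every marker test.
#'
#' `K` must be symmetric positive semi-definite up to numerical noise; small
#' negative eigenvalues (> `-1e-8 * max(eigenvalue)`) are clipped to a tiny
#' jitter and recorded in the returned object, anything worse is an error.
#'
#' @param y named numeric phenotype vector (names = line ids).
#' @param Q optional lines x q matrix of fixed structure covariates, rows
#'   named by line.
#' @param K kinship matrix with dimnames covering the phenotyped lines.
#' @return object of class `mlm_null`: list with the rotated data, the line
#'   ids used, `delta`, `sigma_a2`, `sigma_e2`, `reml_logLik`, `jittered`.
#' @export
mlm_null <- function(y, Q = NULL, K) {
  if (is.null(names(y))) stop("`y` must be named by line id")
  y <- y[!is.na(y)]
  lines <- names(y)
  if (stats::var(y) == 0) stop("phenotype has zero variance")
  if (!all(lines %in% rownames(K)))
    stop("kinship matrix does not cover all phenotyped lines")
  K <- K[lines, lines]
  X <- cbind(`(Intercept)` = rep(1, length(y)))
  if (!is.null(Q)) {
    Q <- as.matrix(Q)
    if (is.null(rownames(Q))) stop("`Q` must have line rownames")
    X <- cbind(X, Q[lines, , drop = FALSE])
  }
  ek <- eigen((K + t(K)) / 2, symmetric = TRUE)
  tol <- 1e-8 * max(ek$values)
  if (min(ek$values) < -0.25 * max(ek$values))
    stop("kinship matrix is not positive semi-definite")
  # moderately negative eigenvalues (a by-product of clipping rules such as
  # negatives-to-zero) are repaired by a diagonal shift: K + cI is model
  # equivalent, the shift being absorbed into the residual variance
  jittered <- any(ek$values < tol)
  shift <- if (min(ek$values) < tol) tol - min(ek$values) else 0
  s <- ek$values + shift
  u <- ek$vectors
  yr <- drop(crossprod(u, y))
  xr <- crossprod(u, X)

  opt <- stats::optimize(function(ld) reml_ll(exp(ld), yr, xr, s),
                         interval = c(-12, 12), maximum = TRUE,
                         tol = .Machine$double.eps^0.5)
  # guard against a local maximum: coarse grid refinement
  grid <- seq(-12, 12, by = 0.5)
  gll <- vapply(grid, function(ld) reml_ll(exp(ld), yr, xr, s), numeric(1))
  if (max(gll) > opt$objective + 1e-6) {
    best <- grid[which.max(gll)]
    opt <- stats::optimize(function(ld) reml_ll(exp(ld), yr, xr, s),
                           interval = c(best - 0.6, best + 0.6),
                           maximum = TRUE, tol = .Machine$double.eps^0.5)
  }
  delta <- exp(opt$maximum)
  wts <- 1 / (s + delta)
  fit <- stats::lm.wfit(xr, yr, wts)
  n <- length(yr)
  q <- fit$rank
  sigma_a2 <- sum(wts * fit$residuals^2) / (n - q)
  structure(list(lines = lines, y = y, X = X, U = u, s = s,
                 y_rot = yr, X_rot = xr, delta = delta, shift = shift,
                 sigma_a2 = sigma_a2, sigma_e2 = sigma_a2 * delta,
                 reml_logLik = opt$objective, jittered = jittered,
                 K = K),
            class = "mlm_null")
}

# Profiled REML log-likelihood in delta after rotation by the eigenvectors
# of K; s are the eigenvalues.
reml_ll <- function(delta, yr, xr, s) {
  wts <- 1 / (s + delta)
  fit <- stats::lm.wfit(xr, yr, wts)
  n <- length(yr)
  q <- fit$rank
  rss <- sum(wts * fit$residuals^2)
  xwx <- crossprod(xr * sqrt(wts))
  xx <- crossprod(xr)
  -0.5 * ((n - q) * (log(2 * pi) + log(rss / (n - q)) + 1) +
            sum(log(s + delta)) +
            determinant(xwx, logarithm = TRUE)$modulus -
            determinant(xx, logarithm = TRUE)$modulus)
}

#' @export
print.mlm_null <- function(x, ...) {
  cat(sprintf(
    "mlm_null: %d lines, sigma_a2 = %.4g, sigma_e2 = %.4g (delta = %.4g)\n",
    length(x$lines), x$sigma_a2, x$sigma_e2, x$delta))
  invisible(x)
}

#' Mixed-model marker test (Q + K, P3D)
#'
#' Tests marker fixed effects in the model of [mlm_null()] with the variance
#' ratio held at its null estimate (P3D). The test is the generalized
#' least-squares F-test comparing the model with and without the marker
#' columns; for a multi-column design (haplotype indicators) it is the joint
#' F-test.
#'
#' Markers observed on all phenotyped lines use the precomputed rotation.
#' A marker with missing lines is handled by omission: the covariance
#' `sigma_a2 (K_ss + delta I)` is re-factored on the observed subset with the
#' null variance ratio reused, and the null model is refit on that subset so
#' the F-test compares nested models on identical data.
#'
#' @param null an `mlm_null` object.
#' @param marker numeric vector or matrix of marker codes, named/rownamed by
#'   line id; `NA` rows are omitted for this marker.
#' @return list with `F`, `df1`, `df2`, `p_value`, `effects` (named GLS
#'   estimates of the marker columns), `n_used`.
#' @export
mlm_marker_test <- function(null, marker) {
  m <- as.matrix(marker)
  if (is.null(rownames(m)))
    stop("`marker` must be named/rownamed by line id")
  m <- m[null$lines, , drop = FALSE]
  ok <- rowSums(is.na(m)) == 0
  if (sum(ok) < ncol(null$X) + ncol(m) + 2)
    return(list(F = NA_real_, df1 = ncol(m), df2 = NA_real_,
                p_value = NA_real_, effects = NULL, n_used = sum(ok)))
  if (all(ok)) {
    mr <- crossprod(null$U, m)
    gls_f_test(null$X_rot, mr, null$y_rot, 1 / (null$s + null$delta))
  } else {
    lines <- null$lines[ok]
    v <- null$K[lines, lines]
    diag(v) <- diag(v) + null$delta + null$shift
    ch <- tryCatch(chol(v), error = function(e)
      chol(v + diag(1e-6, nrow(v))))
    li <- backsolve(ch, diag(nrow(v)), transpose = TRUE)
    gls_f_test(li %*% null$X[ok, , drop = FALSE],
               li %*% m[ok, , drop = FALSE],
               drop(li %*% null$y[ok]),
               rep(1, sum(ok)))
  }
}

# Weighted LS F-test of the extra columns `mr` over the base design `xr`.
gls_f_test <- function(xr, mr, yr, wts) {
  fit0 <- stats::lm.wfit(xr, yr, wts)
  x1 <- cbind(xr, mr)
  fit1 <- stats::lm.wfit(x1, yr, wts)
  rss0 <- sum(wts * fit0$residuals^2)
  rss1 <- sum(wts * fit1$residuals^2)
  df1 <- fit1$rank - fit0$rank
  df2 <- length(yr) - fit1$rank
  if (df1 < 1 || df2 < 1 || rss1 <= 0)
    return(list(F = NA_real_, df1 = df1, df2 = df2, p_value = NA_real_,
                effects = NULL, n_used = length(yr)))
  f <- ((rss0 - rss1) / df1) / (rss1 / df2)
  eff <- fit1$coefficients[seq(ncol(xr) + 1, ncol(x1))]
  names(eff) <- colnames(mr)
  list(F = f, df1 = df1, df2 = df2,
       p_value = stats::pf(f, df1, df2, lower.tail = FALSE),
       effects = eff, n_used = length(yr))
}

#' One-shot mixed-model fit for a single marker
#'
#' Convenience wrapper: runs [mlm_null()] (unless a prefitted null is given)
#' and then [mlm_marker_test()].
#'
#' @inheritParams mlm_null
#' @param marker marker vector/matrix named by line.
#' @param null optional prefitted `mlm_null` (P3D reuse).
#' @return as [mlm_marker_test()], plus the `null` object.
#' @export
mlm_fit <- function(y, marker, Q = NULL, K, null = NULL) {
  if (is.null(null)) null <- mlm_null(y, Q, K)
  out <- mlm_marker_test(null, marker)
  out$null <- null
  out
}

#' Marker R-squared by one-way ANOVA
#'
#' The fraction of phenotypic variation explained reported alongside the
#' mixed-model test: `R^2 = SSA / SST`, the between-group sum of squares of
#' the phenotype grouped by marker class over the total sum of squares.
#' Computed outside the mixed model.
#'
#' @param y numeric phenotype vector.
#' @param groups marker classes (factor/character/numeric), same length;
#'   pairs with `NA` in either are dropped.
#' @return value in `[0, 1]`.
#' @export
marker_r2 <- function(y, groups) {
  ok <- !is.na(y) & !is.na(groups)
  y <- y[ok]
  g <- factor(groups[ok])
  sst <- sum((y - mean(y))^2)
  if (sst == 0) return(0)
  mu <- tapply(y, g, mean)
  n <- tapply(y, g, length)
  ssa <- sum(n * (mu - mean(y))^2)
  ssa / sst
}

#' Significance threshold from the marker count
#'
#' Declares significance at `P < 1/n` for `n` markers tested, with the
#' threshold rounded to two significant digits and its negative log10 (of
#' the unrounded `1/n`) rounded to two decimals, matching the convention of
#' marker-count-based thresholds in association studies of this kind.
#'
#' @param n_markers number of markers tested.
#' @return list with `n_markers`, `threshold`, `neglog10`.
#' @examples
#' significance_rule(4434)  # threshold 2.3e-4, -log10 = 3.65
#' @export
significance_rule <- function(n_markers) {
  if (n_markers < 1) stop("`n_markers` must be >= 1")
  list(n_markers = as.integer(n_markers),
       threshold = signif(1 / n_markers, 2),
       neglog10 = round(log10(n_markers), 2))
}
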