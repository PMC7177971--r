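#' Log-determinant term of the spatial likelihood
#'
#' Computes \eqn{\ln|I - \rho W|} from the (possibly complex) eigenvalues of
#' W as \eqn{\sum_i \ln(1 - \rho \lambda_i)}; imaginary parts cancel over
#' conjugate pairs, so the real part of the sum is returned. For real
#' eigenvalues a nonpositive factor means `rho` is outside the feasible
#' interval and is an error.
#'
#' @param rho scalar spatial autoregressive parameter.
#' @param w a [knn_weights()] object (eigenvalues are computed once and
#'   cached).
#' @return scalar log-determinant.
#' @export
log_det <- function(rho, w) {
  ev <- w_eigenvalues(w)
  f <- 1 - rho * ev
  re <- Re(f)[abs(Im(ev)) < 1e-12]
  if (any(re <= 0)) stop("log_det: 1 - rho*lambda <= 0; rho infeasible")
  Re(sum(log(f)))
}

# feasible interval for rho given W's eigenvalues: (1/min(Re(lambda)), 1)
# for real spectra of row-standardized W, else (-1, 1)
rho_interval <- function(w) {
  ev <- w_eigenvalues(w)
  if (all(abs(Im(ev)) < 1e-8)) {
    lo <- 1 / min(Re(ev))
    c(lo, 1)
  } else c(-1, 1)
}

#' Fit a spatial Durbin model by maximum likelihood
#'
#' Estimates \eqn{y = \rho W y + X\beta + WX\theta + \varepsilon},
#' \eqn{\varepsilon \sim N(0,\sigma^2 I)}, by concentrated (profile)
#' likelihood: for candidate \eqn{\rho}, \eqn{y - \rho Wy} is regressed on
#' \eqn{Z = [1, X, WX]}; the profile log-likelihood
#' \eqn{\ln|I-\rho W| - (n/2)\ln(RSS(\rho)/n) + const} is maximized over the
#' feasible interval determined by W's eigenvalue bounds. The
#' variance-covariance matrix over \eqn{(\beta, \theta, \rho)} comes from the
#' numeric Hessian (central differences) of the full log-likelihood at the
#' optimum, with \eqn{\sigma^2} included in the differentiation and
#' marginalized by inversion.
#'
#' @param y numeric outcome vector (e.g. log10 local use).
#' @param X numeric covariate matrix with column names; no constant columns.
#' @param w a [knn_weights()] object over the same units, row-standardized.
#' @return object of class `sdm_fit` with elements `rho`, `beta` (including
#'   intercept), `theta` (named `lag.<var>`), `coefficients` (the full
#'   `(beta, theta)` vector), `sigma2`, `vcov` (over `(beta, theta, rho)`),
#'   `loglik`, `residuals`, `fitted`, `interval`, `iv_names`, `n`.
#' @export
fit_sdm <- function(y, X, w) {
  X <- as.matrix(X)
  n <- length(y)
  stopifnot(inherits(w, "knn_weights"), w$n == n, nrow(X) == n)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (any(apply(X, 2, stats::sd) == 0))
    stop("fit_sdm: constant column in X (only the intercept may be constant)")
  p <- ncol(X)
  if (n <= 2 * p + 2) stop("fit_sdm: need n > 2p + 2 observations")

  WX <- lag_spatial(w, X)
  colnames(WX) <- paste0("lag.", colnames(X))
  Z <- cbind("(Intercept)" = 1, X, WX)
  qrZ <- qr(Z)
  if (qrZ$rank < ncol(Z)) {
    bad <- colnames(Z)[qrZ$pivot[(qrZ$rank + 1):ncol(Z)]]
    stop("fit_sdm: collinear design [X, WX]; offending column(s): ",
         paste(bad, collapse = ", "))
  }

  Wy <- lag_spatial(w, y)
  e0 <- qr.resid(qrZ, y)
  eL <- qr.resid(qrZ, Wy)
  s00 <- sum(e0^2); s0L <- sum(e0 * eL); sLL <- sum(eL^2)
  rss <- function(rho) s00 - 2 * rho * s0L + rho^2 * sLL

  interval <- rho_interval(w)
  eps <- 1e-6 * diff(interval)
  profile_ll <- function(rho) log_det(rho, w) - (n / 2) * log(rss(rho) / n)
  opt <- stats::optimize(profile_ll, lower = interval[1] + eps,
                         upper = interval[2] - eps, maximum = TRUE,
                         tol = .Machine$double.eps^0.5)
  rho <- opt$maximum
  if (min(rho - interval[1], interval[2] - rho) < 10 * eps)
    stop(sprintf("fit_sdm: optimizer at feasible-interval boundary (rho = %.6f, interval [%.4f, %.4f])",
                 rho, interval[1], interval[2]))

  gamma <- qr.coef(qrZ, y - rho * Wy)
  sigma2 <- rss(rho) / n
  fitted <- drop(Z %*% gamma) + rho * Wy
  resid <- y - fitted
  loglik <- -(n / 2) * (log(2 * pi * sigma2) + 1) + log_det(rho, w)

  # full log-likelihood over (gamma, rho, sigma2) via cross-products (O(p^2))
  ZtZ <- crossprod(Z); Zty <- crossprod(Z, y); ZtWy <- crossprod(Z, Wy)
  yty <- sum(y^2); ytWy <- sum(y * Wy); WytWy <- sum(Wy^2)
  ll_full <- function(par) {
    g <- par[seq_len(ncol(Z))]
    r <- par[ncol(Z) + 1L]
    s2 <- par[ncol(Z) + 2L]
    if (s2 <= 0 || r <= interval[1] || r >= interval[2]) return(-Inf)
    sse <- yty - 2 * r * ytWy + r^2 * WytWy -
      2 * sum(g * (Zty - r * ZtWy)) + drop(t(g) %*% ZtZ %*% g)
    -(n / 2) * log(2 * pi * s2) + log_det(r, w) - sse / (2 * s2)
  }
  par <- c(gamma, rho, sigma2)
  h <- 1e-5 * pmax(abs(par), 1)
  h[length(par)] <- 1e-5 * sigma2  # keep sigma2 steps strictly positive
  H <- num_hessian(ll_full, par, h = h)
  if (!all(is.finite(H)))
    stop("fit_sdm: non-finite Hessian of the log-likelihood (near-degenerate fit)")
  # Jacobi-scaled inversion: parameter scales differ by many orders of
  # magnitude when sigma2 is small, so precondition before solving
  d <- sqrt(abs(diag(H)))
  if (any(d == 0)) stop("fit_sdm: information matrix is singular (zero curvature)")
  Hs <- H / tcrossprod(d)
  vc_full <- tryCatch(solve(-Hs) / tcrossprod(d), error = function(e)
    stop("fit_sdm: information matrix is singular: ", conditionMessage(e)))
  keep <- seq_len(ncol(Z) + 1L)
  vcov <- (vc_full[keep, keep] + t(vc_full[keep, keep])) / 2
  dimnames(vcov) <- list(c(colnames(Z), "rho"), c(colnames(Z), "rho"))

  structure(list(
    rho = rho,
    coefficients = gamma,
    beta = gamma[c("(Intercept)", colnames(X))],
    theta = gamma[colnames(WX)],
    sigma2 = sigma2,
    vcov = vcov,
    loglik = loglik,
    residuals = resid,
    fitted = fitted,
    interval = interval,
    iv_names = colnames(X),
    n = n
  ), class = "sdm_fit")
}

# central-difference Hessian, relative step (or explicit per-coordinate steps)
num_hessian <- function(f, par, rel_step = 1e-5, h = NULL) {
  p <- length(par)
  h <- h %||% (rel_step * pmax(abs(par), 1))
  H <- matrix(NA_real_, p, p)
  for (i in seq_len(p)) {
    for (j in i:p) {
      if (i == j) {
        pp <- par; pp[i] <- par[i] + h[i]; f1 <- f(pp)
        pp[i] <- par[i] - h[i]; f2 <- f(pp)
        H[i, i] <- (f1 - 2 * f(par) + f2) / h[i]^2
      } else {
        pp <- par
        pp[i] <- par[i] + h[i]; pp[j] <- par[j] + h[j]; fpp <- f(pp)
        pp[j] <- par[j] - h[j]; fpm <- f(pp)
        pp[i] <- par[i] - h[i]; fmm <- f(pp)
        pp[j] <- par[j] + h[j]; fmp <- f(pp)
        H[i, j] <- H[j, i] <- (fpp - fpm - fmp + fmm) / (4 * h[i] * h[j])
      }
    }
  }
  H
}

#' @export
print.sdm_fit <- function(x, ...) {
  cat(sprintf("<sdm_fit> n = %d, rho = %.4f, sigma2 = %.4f, logLik = %.2f\n",
              x$n, x$rho, x$sigma2, x$loglik))
  se <- sqrt(diag(x$vcov))
  est <- c(x$coefficients, rho = x$rho)
  print(data.frame(estimate = round(est, 4), std_error = round(se, 4)))
  invisible(x)
}

#' Fit summary as a tidy data frame
#'
#' @param fit an [fit_sdm()] result.
#' @return data frame `term`, `estimate`, `std_error`.
#' @export
sdm_tidy <- function(fit) {
  est <- c(fit$coefficients, rho = fit$rho)
  data.frame(term = names(est), estimate = unname(est),
             std_error = sqrt(diag(fit$vcov)), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Dense (exact) direct, indirect and total impacts
#'
#' Oracle impact computation by dense inversion: for IV k,
#' \eqn{S_k = (I - \rho W)^{-1}(I\beta_k + W\theta_k)}; the direct impact is
#' the mean diagonal of \eqn{S_k}, the total impact the mean row sum, and
#' indirect = total - direct. Intended for n up to a couple thousand.
#'
#' @param fit an [fit_sdm()] result (or a list with `rho`, `beta`, `theta`,
#'   `iv_names`).
#' @param w the [knn_weights()] used in the fit.
#' @return matrix with one row per IV and columns `direct`, `indirect`,
#'   `total`.
#' @export
impacts_dense <- function(fit, w) {
  n <- w$n
  Wd <- as.matrix(w$W)
  A <- diag(n) - fit$rho * Wd
  if (rcond(A) < 1e-14) stop("impacts_dense: (I - rho W) is singular")
  Ainv <- solve(A)
  AinvW <- Ainv %*% Wd
  mdiag_A <- mean(diag(Ainv)); mdiag_AW <- mean(diag(AinvW))
  mrow_A <- mean(rowSums(Ainv)); mrow_AW <- mean(rowSums(AinvW))
  out <- t(vapply(fit$iv_names, function(v) {
    b <- fit$beta[[v]]; th <- fit$theta[[paste0("lag.", v)]]
    direct <- b * mdiag_A + th * mdiag_AW
    total <- b * mrow_A + th * mrow_AW
    c(direct = direct, indirect = total - direct, total = total)
  }, numeric(3)))
  rownames(out) <- fit$iv_names
  out
}

# trace-series impacts for one (beta, theta, rho) draw; tr = tr(W^j)/n for
# j = 0..q+1; total uses the row-standardized closed form
impacts_trace <- function(beta, theta, rho, tr, q) {
  rp <- rho^(0:q)
  direct <- vapply(seq_along(beta), function(k)
    sum(rp * (beta[k] * tr[1:(q + 1)] + theta[k] * tr[2:(q + 2)])), numeric(1))
  total <- (beta + theta) / (1 - rho)
  cbind(direct = direct, indirect = total - direct, total = total)
}

#' Monte Carlo impact draws via traces of powers of W
#'
#' Draws \eqn{(\beta, \theta, \rho)} from the multivariate normal centered
#' at the estimates with covariance `fit$vcov` (draws with \eqn{\rho}
#' outside the feasible interval are rejected and redrawn, up to 1000
#' attempts each), and for each draw computes impacts from the truncated
#' power series with precomputed trace ratios \eqn{tr(W^j)/n}:
#' \deqn{direct_k \approx \sum_{j=0}^{q} \rho^j\,(\beta_k\,tr(W^j) +
#'   \theta_k\,tr(W^{j+1}))/n,}
#' with the total impact from the row-standardized closed form
#' \eqn{(\beta_k + \theta_k)/(1 - \rho)} and indirect = total - direct.
#'
#' @param fit an [fit_sdm()] result.
#' @param w the [knn_weights()] used in the fit.
#' @param n_draws number of Monte Carlo draws (default 100).
#' @param seed integer seed.
#' @param q truncation order of the trace series (default 30).
#' @return object of class `impact_draws`: matrices `direct`, `indirect`,
#'   `total` (`n_draws` rows, one column per IV) and `n_draws`.
#' @export
impacts_mc <- function(fit, w, n_draws = 100L, seed = 1L, q = 30L) {
  stopifnot(n_draws >= 1, q >= 1)
  tr <- w_trace_ratios(w, q + 1L)
  ivs <- fit$iv_names
  kk <- length(ivs)
  mu <- c(fit$coefficients, fit$rho)
  Sigma <- fit$vcov
  set.seed(derive_seed(seed, "impacts_mc"))

  if (max(abs(Sigma)) == 0) {
    pars <- matrix(mu, n_draws, length(mu), byrow = TRUE)
  } else {
    es <- eigen(Sigma, symmetric = TRUE)
    d <- es$values
    if (min(d) < -1e-8 * max(abs(d))) {
      warning("impacts_mc: vcov not positive semidefinite; clipping negative eigenvalues")
    }
    L <- es$vectors %*% diag(sqrt(pmax(d, 0)), length(d))
    draw_par <- function() drop(mu + L %*% stats::rnorm(length(mu)))
    pars <- matrix(NA_real_, n_draws, length(mu))
    for (i in seq_len(n_draws)) {
      ok <- FALSE
      for (attempt in seq_len(1000L)) {
        cand <- draw_par()
        r <- cand[length(cand)]
        if (r > fit$interval[1] && r < fit$interval[2]) { ok <- TRUE; break }
      }
      if (!ok) stop("impacts_mc: could not draw rho inside the feasible interval in 1000 attempts")
      pars[i, ] <- cand
    }
  }

  direct <- indirect <- total <- matrix(NA_real_, n_draws, kk,
                                        dimnames = list(NULL, ivs))
  b_idx <- match(ivs, names(fit$coefficients))
  t_idx <- match(paste0("lag.", ivs), names(fit$coefficients))
  for (i in seq_len(n_draws)) {
    imp <- impacts_trace(pars[i, b_idx], pars[i, t_idx],
                         pars[i, ncol(pars)], tr, q)
    direct[i, ] <- imp[, "direct"]
    indirect[i, ] <- imp[, "indirect"]
    total[i, ] <- imp[, "total"]
  }
  structure(list(direct = direct, indirect = indirect, total = total,
                 n_draws = n_draws, iv_names = ivs),
            class = "impact_draws")
}

#' @export
print.impact_draws <- function(x, ...) {
  cat(sprintf("<impact_draws> %d draws x %d IVs (median total shown)\n",
              x$n_draws, length(x$iv_names)))
  print(round(apply(x$total, 2, stats::median), 4))
  invisible(x)
}
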