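#' Fit a univariate equal-variance Gaussian mixture ("model E") by EM
#'
#' The DBEC background model: K in 1..3 Gaussian components sharing a single
#' common variance. Fitting is plain EM with deterministic quantile-split
#' initialization plus seeded random restarts; the best log-likelihood wins.
#' Components are returned sorted by increasing mean, so component indices
#' are stable and deterministic.
#'
#' At K = 1 the EM reduces to the closed form: mean = sample mean, shared
#' variance = the (1/n) maximum-likelihood variance.
#'
#' @param values Numeric observations (transformed expression values).
#' @param K Number of components (1, 2 or 3 in the DBEC range, but any
#'   K >= 1 with `n >= 5 K` is accepted).
#' @param max_iter Maximum EM iterations (default 500).
#' @param tol Relative log-likelihood convergence tolerance (default 1e-8).
#' @param n_restarts Total initializations: 1 quantile split +
#'   `n_restarts - 1` random (default 5).
#' @param seed Integer seed for the random restarts.
#' @return A `mixture_fit` object: `K`, `weights`, `means` (ascending),
#'   `shared_variance`, `loglik`, `bic`, `responsibilities` (n x K),
#'   `loglik_trace` (per-iteration log-likelihoods of the winning run),
#'   `n`. BIC is `-2 loglik + p log n` with `p = (K - 1) + K + 1` free
#'   parameters.
#' @export
fit_mixture_model_e <- function(values, K, max_iter = 500L, tol = 1e-8,
                                n_restarts = 5L, seed = 1L) {
  x <- as.numeric(values)
  n <- length(x)
  K <- as.integer(K)
  stopifnot(K >= 1L)
  if (n < 5L * K) {
    stop("fit_mixture_model_e: need n >= 5*K observations (n=", n,
         ", K=", K, ")")
  }
  if (K == 1L) {
    mu <- mean(x)
    v <- max(mean((x - mu)^2), 1e-8)
    ll <- sum(stats::dnorm(x, mu, sqrt(v), log = TRUE))
    return(new_mixture_fit(K = 1L, weights = 1, means = mu, var = v,
                           loglik = ll, resp = matrix(1, n, 1),
                           trace = ll, n = n))
  }
  inits <- list(quantile_init(x, K))
  if (n_restarts > 1L) {
    rand <- with_local_seed(seed, replicate(n_restarts - 1L, {
      list(means = sort(sample(x, K)), var = max(stats::var(x), 1e-8),
           weights = rep(1 / K, K))
    }, simplify = FALSE))
    inits <- c(inits, rand)
  }
  best <- NULL
  for (init in inits) {
    fit <- em_run(x, K, init, max_iter, tol)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  new_mixture_fit(K = K, weights = best$weights, means = best$means,
                  var = best$var, loglik = best$loglik, resp = best$resp,
                  trace = best$trace, n = n)
}

quantile_init <- function(x, K) {
  qs <- stats::quantile(x, probs = seq(0, 1, length.out = K + 1L),
                        names = FALSE)
  grp <- pmin(findInterval(x, qs[-c(1, K + 1L)]) + 1L, K)
  means <- as.numeric(tapply(x, factor(grp, levels = 1:K), mean))
  means[is.na(means)] <- mean(x)
  v <- max(mean((x - means[grp])^2, na.rm = TRUE), 1e-8)
  list(means = means, var = v, weights = rep(1 / K, K))
}

# EM on the weighted unique values: counts are discrete, so collapsing to
# (unique value, multiplicity) pairs is an exact reformulation of the
# likelihood and its EM updates, not an approximation.
em_run <- function(x, K, init, max_iter, tol) {
  ux <- sort(unique(x))
  wt <- as.numeric(table(factor(x, levels = ux)))
  n <- length(x)
  m_u <- length(ux)
  mu <- init$means
  v <- init$var
  w <- init$weights
  trace <- numeric(0)
  ll_old <- -Inf
  resp <- matrix(1 / K, m_u, K)
  for (iter in seq_len(max_iter)) {
    # E step in log space for stability
    lconst <- -0.5 * log(2 * pi * v)
    lw <- outer(ux, mu, function(xx, m) lconst - (xx - m)^2 / (2 * v)) +
      matrix(log(pmax(w, 1e-300)), m_u, K, byrow = TRUE)
    mx <- lw[, 1L]
    for (k in seq_len(K)[-1L]) mx <- pmax(mx, lw[, k])
    lse <- mx + log(rowSums(exp(lw - mx)))
    ll <- sum(wt * lse)
    trace <- c(trace, ll)
    resp <- exp(lw - lse)
    if (is.finite(ll_old) && abs(ll - ll_old) <= tol * (1 + abs(ll))) break
    ll_old <- ll
    # M step (shared variance)
    nk <- colSums(wt * resp)
    w <- nk / n
    mu <- ifelse(nk > 0, colSums(wt * resp * ux) / nk, mu)
    v <- sum(wt * resp * (outer(ux, mu, "-"))^2) / n
    if (v < 1e-8) {
      warning("fit_mixture_model_e: variance underflow, floored at 1e-8")
      v <- 1e-8
    }
  }
  ord <- order(mu)
  list(weights = w[ord], means = mu[ord], var = v, loglik = ll,
       resp = resp[match(x, ux), ord, drop = FALSE], trace = trace)
}

new_mixture_fit <- function(K, weights, means, var, loglik, resp, trace, n) {
  p <- (K - 1L) + K + 1L
  structure(list(K = K, weights = as.numeric(weights),
                 means = as.numeric(means), shared_variance = var,
                 loglik = loglik, bic = -2 * loglik + p * log(n),
                 responsibilities = resp, loglik_trace = trace, n = n),
            class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("mixture_fit (model E): K=%d, means=%s, sd=%.4g, loglik=%.4f, BIC=%.2f\n",
              x$K, paste(sprintf("%.3f", x$means), collapse = "/"),
              sqrt(x$shared_variance), x$loglik, x$bic))
  invisible(x)
}

#' Select a mixture fit by BIC
#'
#' Minimal BIC wins; ties break toward the smaller K (the more parsimonious
#' model).
#'
#' @param fits List of `mixture_fit` objects (e.g. over K = 1..3).
#' @return The selected `mixture_fit`.
#' @export
select_model_bic <- function(fits) {
  if (!length(fits)) stop("select_model_bic: no fits supplied")
  bics <- vapply(fits, function(f) f$bic, 1)
  ks <- vapply(fits, function(f) f$K, 1L)
  ord <- order(bics, ks)
  fits[[ord[1]]]
}
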