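# Fold-change and FDR threshold derivation: three-component Gaussian mixture
# fitted to the empirical log2 fold-change distribution, crossover points of
# adjacent weighted components as calling thresholds, and the inflection of
# the count-vs-FDR curve.

# Crossing point of two weighted Gaussian densities w1*phi(m1,s1) and
# w2*phi(m2,s2) inside the open interval (m1, m2). The equality of weighted
# log-densities is quadratic in x, so the crossing is solved in closed form.
gaussian_crossing <- function(w1, m1, s1, w2, m2, s2) {
  stopifnot(m1 < m2, s1 > 0, s2 > 0, w1 > 0, w2 > 0)
  A <- 1 / (2 * s2^2) - 1 / (2 * s1^2)
  B <- m1 / s1^2 - m2 / s2^2
  C <- m2^2 / (2 * s2^2) - m1^2 / (2 * s1^2) + log((w1 * s2) / (w2 * s1))
  roots <- if (abs(A) < .Machine$double.eps * max(1 / s1^2, 1 / s2^2)) {
    if (B == 0) numeric(0) else -C / B
  } else {
    disc <- B^2 - 4 * A * C
    if (disc < 0) numeric(0) else (-B + c(-1, 1) * sqrt(disc)) / (2 * A)
  }
  roots <- roots[roots > m1 & roots < m2]
  if (length(roots) == 0) {
    stop("no crossover between components with means ", signif(m1, 4), " and ",
         signif(m2, 4), ": one component dominates the whole interval")
  }
  roots[1]
}

#' Fit a three-component Gaussian mixture by EM
#'
#' Fits a sum of three Gaussian functions to a sample of (typically log2
#' fold-change) values with the expectation-maximization algorithm.
#' Initialization is deterministic (means at the 10th/50th/90th percentiles,
#' equal weights); the seed only perturbs restarts after a component
#' collapses below `sd_floor`. Components are reported sorted by mean.
#'
#' @param values Numeric vector (at least 30 values).
#' @param seed Integer seed used only for collapse restarts.
#' @param max_iter Maximum EM iterations.
#' @param tol Relative log-likelihood convergence tolerance.
#' @param sd_floor Component SD below which a fit counts as collapsed.
#' @return A `mixfit3` object: `weights`, `means`, `sds`, `loglik`, `n_iter`,
#'   `converged`, `n`.
#' @export
fit_three_gaussians <- function(values, seed = 1, max_iter = 500, tol = 1e-8,
                                sd_floor = 1e-3) {
  values <- values[is.finite(values)]
  stopifnot(length(values) >= 30)
  n <- length(values)

  run_em <- function(mu, sg, w) {
    ll_prev <- -Inf
    for (it in seq_len(max_iter)) {
      # E step in log space for numerical stability
      lg <- vapply(1:3, function(k) {
        log(w[k]) + stats::dnorm(values, mu[k], sg[k], log = TRUE)
      }, numeric(n))
      mx <- apply(lg, 1, max)
      lse <- mx + log(rowSums(exp(lg - mx)))
      ll <- sum(lse)
      if (ll + 1e-9 < ll_prev) {
        stop("EM log-likelihood decreased; numerical failure")
      }
      r <- exp(lg - lse)
      nk <- colSums(r)
      w <- nk / n
      mu <- colSums(r * values) / nk
      sg <- sqrt(colSums(r * (values - rep(mu, each = n))^2) / nk)
      if (any(!is.finite(sg)) || any(sg < sd_floor)) {
        return(list(collapsed = TRUE))
      }
      if (abs(ll - ll_prev) < tol * (1 + abs(ll))) {
        return(list(collapsed = FALSE, mu = mu, sg = sg, w = w, ll = ll,
                    it = it, converged = TRUE))
      }
      ll_prev <- ll
    }
    list(collapsed = FALSE, mu = mu, sg = sg, w = w, ll = ll_prev,
         it = max_iter, converged = FALSE)
  }

  mu0 <- unname(stats::quantile(values, c(0.1, 0.5, 0.9)))
  sg0 <- rep(max(stats::sd(values) / 2, sd_floor), 3)
  fit <- run_em(mu0, sg0, rep(1 / 3, 3))
  restarts <- 0
  while (isTRUE(fit$collapsed)) {
    restarts <- restarts + 1
    if (restarts > 5) {
      stop("mixture component collapsed below sd_floor in 5 restarts; ",
           "values may be (near-)degenerate")
    }
    fit <- withr::with_seed(seed + restarts, {
      jit <- stats::rnorm(3, 0, max(stats::sd(values), sd_floor))
      run_em(sort(mu0 + jit), sg0 * stats::runif(3, 0.5, 2), rep(1 / 3, 3))
    })
  }
  ord <- order(fit$mu)
  structure(
    list(weights = fit$w[ord], means = fit$mu[ord], sds = fit$sg[ord],
         loglik = fit$ll, n_iter = fit$it, converged = fit$converged, n = n),
    class = "mixfit3"
  )
}

#' @export
print.mixfit3 <- function(x, ...) {
  cat("Three-component Gaussian mixture fit (n =", x$n, ")\n")
  cat(sprintf("  component %d: weight %.3f, mean %7.3f, sd %.3f\n",
              1:3, x$weights, x$means, x$sds), sep = "")
  cat(sprintf("  loglik %.2f after %d iterations (%s)\n", x$loglik, x$n_iter,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Tidy a mixture fit
#' @param x A `mixfit3` object.
#' @param ... Unused.
#' @return One row per component: `component`, `weight`, `mean`, `sd`.
#' @method tidy mixfit3
#' @export
tidy.mixfit3 <- function(x, ...) {
  tibble(component = 1:3, weight = x$weights, mean = x$means, sd = x$sds)
}

#' One-row summary of a mixture fit
#' @param x A `mixfit3` object.
#' @param ... Unused.
#' @return Tibble with `loglik`, `n_iter`, `converged`, `n`.
#' @method glance mixfit3
#' @export
glance.mixfit3 <- function(x, ...) {
  tibble(loglik = x$loglik, n_iter = x$n_iter, converged = x$converged,
         n = x$n)
}

#' Fold-change thresholds from mixture crossover points
#'
#' Determines the lower and upper calling thresholds as the intersections of
#' the fitted Gaussian components: the lower threshold is where the weighted
#' densities of components 1 and 2 cross (between their means), the upper
#' where components 2 and 3 cross. With `weighted = FALSE` the crossing of
#' unit-weight densities is used instead.
#'
#' @param fit A `mixfit3` object (converged, distinct means).
#' @param weighted Use mixture-weighted component densities (default) or raw
#'   densities.
#' @return One-row tibble with `lower` and `upper`.
#' @export
crossover_points <- function(fit, weighted = TRUE) {
  stopifnot(inherits(fit, "mixfit3"))
  if (!fit$converged) stop("mixture fit did not converge")
  if (min(diff(fit$means)) <= 0) stop("component means are not distinct")
  w <- if (weighted) fit$weights else rep(1, 3)
  lower <- gaussian_crossing(w[1], fit$means[1], fit$sds[1],
                             w[2], fit$means[2], fit$sds[2])
  upper <- gaussian_crossing(w[2], fit$means[2], fit$sds[2],
                             w[3], fit$means[3], fit$sds[3])
  dens <- function(k, x) w[k] * stats::dnorm(x, fit$means[k], fit$sds[k])
  stopifnot(abs(dens(1, lower) - dens(2, lower)) < 1e-10,
            abs(dens(2, upper) - dens(3, upper)) < 1e-10)
  tibble(lower = lower, upper = upper)
}

#' FDR threshold from the inflection of the discovery curve
#'
#' Builds the curve N(t) = number of q-values at most t on a uniform grid over
#' (0, max q], smooths it with a fixed-width moving average, and returns the
#' grid point of maximum absolute discrete curvature (second difference) -
#' the point where additional FDR relaxation stops yielding discoveries at
#' the initial rate.
#'
#' @param qvalues Numeric vector of FDR q-values in \[0, 1\].
#' @param grid_points Number of grid points.
#' @param smooth_window Moving-average width (grid points, odd).
#' @return The threshold (a grid value).
#' @export
fdr_inflection <- function(qvalues, grid_points = 200, smooth_window = 5) {
  stopifnot(all(qvalues >= 0 & qvalues <= 1), length(qvalues) > 0)
  dq <- unique(qvalues)
  if (length(dq) == 1) return(dq)  # degenerate step: all mass at one value
  if (length(dq) < grid_points / 10) {
    stop("only ", length(dq), " distinct q-values: too few for a stable ",
         "inflection estimate; choose a threshold directly")
  }
  sq <- sort(qvalues)
  tgrid <- seq(max(sq) / grid_points, max(sq), length.out = grid_points)
  N <- findInterval(tgrid, sq)
  k <- rep(1 / smooth_window, smooth_window)
  Ns <- as.numeric(stats::filter(N, k, sides = 2))
  Ns[is.na(Ns)] <- N[is.na(Ns)]
  d2 <- abs(diff(Ns, differences = 2))
  # a near-uniform q distribution has only counting-noise curvature, well
  # below 1% of the total discovery count
  if (max(d2) < 0.01 * max(N)) {
    warning("discovery curve has no clear inflection (near-uniform ",
            "q-values); returning the first grid point")
    return(tgrid[1])
  }
  tgrid[which.max(d2) + 1L]
}
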