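#' Filter targets for Dirichlet fitting
#'
#' Retains targets whose counts are numerically stable for the
#' log-likelihood: by default every subject's count must lie in
#' `[min, max]` (which guarantees strictly positive proportions); with
#' `scope = "pool"` the bounds apply to the pool-summed counts instead.
#'
#' @param counts A [cnv_counts()] matrix.
#' @param min,max Inclusive count bounds (defaults 5 and 2000).
#' @param scope `"subject"` (every sample within bounds, default) or
#'   `"pool"` (bounds on the per-target pool sum).
#' @return The reduced `cnv_counts` with attributes `n_retained` and
#'   `n_dropped`.
#' @export
filter_targets_for_fit <- function(counts, min = 5, max = 2000,
                                   scope = c("subject", "pool")) {
  scope <- match.arg(scope)
  if (ncol(counts) < 2) stop("a pool needs at least 2 subjects")
  C <- unclass(counts)
  keep <- if (scope == "subject") {
    rowSums(C >= min & C <= max) == ncol(C)
  } else {
    rs <- rowSums(C)
    rs >= min & rs <= max
  }
  if (!any(keep))
    stop("no targets pass the [", min, ", ", max, "] count filter; ",
         "loosen the bounds for this pool")
  out <- cnv_counts(C[keep, , drop = FALSE],
                    targets = targets(counts)[keep, , drop = FALSE],
                    subjects = colnames(counts))
  attr(out, "n_retained") <- sum(keep)
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Maximum-likelihood Dirichlet fit to a pool's capture proportions
#'
#' Treats each subject's per-target proportion vector (counts divided by
#' the subject total over the retained targets) as a draw from a
#' Dirichlet distribution and estimates the parameter vector `alpha` by
#' Newton-Raphson on the log-likelihood, using digamma/trigamma
#' derivatives, a moment-matching start, and the diagonal-plus-rank-one
#' structure of the Hessian for linear-time steps. The precision
#' `alpha0 = sum(alpha)` is inversely related to inter-sample variance,
#' so larger fitted `alpha0` means tighter capture balance across the
#' pool.
#'
#' @param counts A filtered [cnv_counts()] matrix (see
#'   [filter_targets_for_fit()]); all counts must be positive.
#' @param max_iter Newton iteration cap.
#' @param tol Convergence tolerance on the gradient max-norm (per
#'   observation).
#' @return A `dirichletfit`: `alpha`, `alpha0`, `mean_alpha`, `loglik`,
#'   `iterations`, `converged`, `n_targets`, `n_subjects`. A fit hitting
#'   the iteration cap is returned as provisional with a warning.
#' @export
fit_dirichlet <- function(counts, max_iter = 1000L, tol = 1e-8) {
  C <- unclass(counts)
  if (ncol(C) < 2) stop("a pool needs at least 2 subjects")
  if (any(C <= 0))
    stop("all counts must be positive; apply filter_targets_for_fit() first")
  P <- sweep(C, 2, colSums(C), "/")       # proportions, one column per subject
  N <- ncol(P); J <- nrow(P)
  logpbar <- rowMeans(log(P))

  ## Moment-matching start (mean/variance of the proportions)
  m <- rowMeans(P)
  v <- apply(P, 1, stats::var)
  ok <- v > 0 & m > 0 & m < 1
  a0 <- if (any(ok)) {
    stats::median(m[ok] * (1 - m[ok]) / v[ok] - 1)
  } else J  # degenerate (identical proportion vectors): neutral start
  a0 <- max(a0, J * 1e-3)
  alpha <- pmax(m * a0, 1e-8)

  loglik <- function(a) {
    N * (lgamma(sum(a)) - sum(lgamma(a))) + sum((a - 1) * N * logpbar)
  }
  ll <- loglik(alpha)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    a0 <- sum(alpha)
    if (a0 > 1e8) break  # divergent precision: zero-variance degenerate pool
    g <- N * (digamma(a0) - digamma(alpha) + logpbar)
    if (max(abs(g)) / N < tol) { converged <- TRUE; break }
    q <- -N * trigamma(alpha)            # Hessian diagonal
    z <- N * trigamma(a0)                # rank-one component
    b <- z * sum(g / q) / (1 + z * sum(1 / q))
    step <- (g - b) / q
    new <- alpha - step
    h <- 1
    while (any(new <= 0) && h > 1e-10) { h <- h / 2; new <- alpha - h * step }
    if (any(new <= 0)) break
    ll_new <- loglik(new)
    while (ll_new < ll - 1e-10 && h > 1e-10) {
      h <- h / 2
      new <- alpha - h * step
      ll_new <- loglik(new)
    }
    if (max(abs(new - alpha)) < 1e-14 * max(1, max(alpha))) {
      alpha <- new; ll <- ll_new
      converged <- max(abs(g)) / N < tol * 100
      break
    }
    alpha <- new
    ll <- ll_new
  }
  if (!converged)
    warning("Dirichlet fit did not converge in ", it,
            " iterations; estimates are provisional")
  structure(list(alpha = alpha, alpha0 = sum(alpha),
                 mean_alpha = mean(alpha), loglik = ll,
                 iterations = it, converged = converged,
                 n_targets = J, n_subjects = N),
            class = "dirichletfit")
}

#' @export
print.dirichletfit <- function(x, ...) {
  cat("Dirichlet fit to capture proportions\n")
  cat(sprintf("  %d subjects, %d retained targets\n", x$n_subjects,
              x$n_targets))
  cat(sprintf("  alpha0 = %.4g  (mean alpha = %.4g)\n", x$alpha0,
              x$mean_alpha))
  cat(sprintf("  log-likelihood %.4g after %d iteration(s)%s\n", x$loglik,
              x$iterations,
              if (x$converged) "" else "  [provisional - not converged]"))
  invisible(x)
}

#' Per-target mean-variance profile of a pool
#'
#' Across-subject sample mean and variance of the counts at each target,
#' with an ordinary least squares fit of variance on mean. Under a pure
#' Poisson capture process variance equals mean (slope 1); excess slope
#' or curvature measures inter-sample overdispersion.
#'
#' @param counts A [cnv_counts()] matrix (>= 2 subjects).
#' @return An `mv_profile`: data frame of per-target `mean` and
#'   `variance` plus `slope`, `intercept` of the OLS fit and the Poisson
#'   reference slope 1.
#' @export
mean_variance_profile <- function(counts) {
  C <- unclass(counts)
  if (ncol(C) < 2) stop("a pool needs at least 2 subjects")
  m <- rowMeans(C)
  v <- apply(C, 1, stats::var)
  if (stats::var(m) == 0) {
    # means are collinear: no regression to fit
    slope <- 0; intercept <- mean(v)
  } else {
    fit <- stats::lm(v ~ m)
    slope <- unname(stats::coef(fit)[2])
    intercept <- unname(stats::coef(fit)[1])
  }
  structure(list(profile = data.frame(target_id = rownames(C), mean = m,
                                      variance = v,
                                      stringsAsFactors = FALSE),
                 slope = slope, intercept = intercept,
                 poisson_slope = 1),
            class = "mv_profile")
}

#' @export
print.mv_profile <- function(x, ...) {
  cat("Mean-variance profile\n")
  cat(sprintf("  %d targets; OLS: variance = %.4g + %.4g * mean\n",
              nrow(x$profile), x$intercept, x$slope))
  cat("  (Poisson reference slope: 1)\n")
  invisible(x)
}

#' @export
plot.mv_profile <- function(x, ...) {
  graphics::plot(x$profile$mean, x$profile$variance, log = "xy",
                 pch = 16, cex = 0.4, col = "grey40",
                 xlab = "mean count", ylab = "variance", ...)
  graphics::abline(0, 1, lty = 2, col = "grey")          # Poisson 1:1
  o <- order(x$profile$mean)
  pred <- x$intercept + x$slope * x$profile$mean[o]
  ok <- pred > 0 & x$profile$mean[o] > 0
  graphics::lines(x$profile$mean[o][ok], pred[ok], lty = 3,
                  col = "firebrick")
  invisible(x)
}
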