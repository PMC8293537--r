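#' Negative binomial log-likelihood in mean/dispersion form
#'
#' Parameterization: mean `m`, dispersion `phi`, variance `m + phi m^2`.
#' `phi = 0` reduces exactly to the Poisson log-pmf. All arguments are
#' recycled to a common length.
#'
#' @param x Non-negative integer counts.
#' @param mean Expected counts (> 0).
#' @param dispersion Overdispersion (>= 0).
#' @return Log-probabilities, same shape as the recycled inputs.
#' @export
nb_loglik <- function(x, mean, dispersion) {
  n <- max(length(x), length(mean), length(dispersion))
  x <- rep_len(as.numeric(x), n)
  m <- rep_len(as.numeric(mean), n)
  phi <- rep_len(as.numeric(dispersion), n)
  out <- numeric(n)
  pois <- phi <= 0
  if (any(pois)) out[pois] <- stats::dpois(x[pois], m[pois], log = TRUE)
  if (any(!pois))
    out[!pois] <- stats::dnbinom(x[!pois], size = 1 / phi[!pois],
                                 mu = m[!pois], log = TRUE)
  out
}

## NB cdf under the same parameterization (phi = 0 -> Poisson)
nb_cdf <- function(q, mean, dispersion, lower.tail = TRUE) {
  n <- max(length(q), length(mean), length(dispersion))
  q <- rep_len(as.numeric(q), n)
  m <- rep_len(as.numeric(mean), n)
  phi <- rep_len(as.numeric(dispersion), n)
  out <- numeric(n)
  pois <- phi <= 0
  if (any(pois))
    out[pois] <- stats::ppois(q[pois], m[pois], lower.tail = lower.tail)
  if (any(!pois))
    out[!pois] <- stats::pnbinom(q[!pois], size = 1 / phi[!pois],
                                 mu = m[!pois], lower.tail = lower.tail)
  out
}

#' Copy-state-adjusted counts
#'
#' Divides observed counts by the current copy-state estimates, putting
#' each subject-target cell on the diploid scale. Cells with state 0 are
#' masked (`NA`) and excluded downstream.
#'
#' @param counts Count matrix (targets x subjects).
#' @param states Copy-state matrix, same shape.
#' @return Numeric matrix of adjusted counts with `NA` where state is 0.
#' @export
adjusted_counts <- function(counts, states) {
  stopifnot(all(dim(counts) == dim(states)))
  cp <- unclass(counts) / states
  cp[states == 0] <- NA_real_
  cp
}

#' Median-of-ratios size factors
#'
#' For each subject, the size factor is the median over qualifying
#' targets of the adjusted count divided by the target's geometric mean
#' across subjects. Only cells with adjusted count above `min_count`
#' enter the median; targets whose geometric mean is zero (some retained
#' subject has a zero) are excluded.
#'
#' @param cprime Adjusted count matrix (may contain `NA` masks).
#' @param min_count Subset threshold: cells must exceed this value.
#' @return Named numeric vector of positive size factors, one per subject.
#' @export
size_factors <- function(cprime, min_count = 10) {
  lg <- log(cprime)
  g <- exp(rowMeans(lg, na.rm = TRUE))  # -Inf log from zeros -> g = 0
  g[!is.finite(g)] <- 0
  ratio <- cprime / g
  use <- !is.na(cprime) & cprime > min_count & g > 0
  f <- vapply(seq_len(ncol(cprime)), function(i) {
    v <- ratio[use[, i], i]
    if (!length(v)) {
      nm <- colnames(cprime)[i]
      stop("no targets qualify for the size factor of subject ",
           if (is.null(nm)) i else nm)
    }
    stats::median(v)
  }, numeric(1))
  names(f) <- colnames(cprime)
  f
}

#' Method-of-moments mean and dispersion per target
#'
#' On size-factor-normalized adjusted counts, computes for each target
#' the sample mean and sample variance across subjects and the
#' method-of-moments dispersion `max(0, (var - mean)/mean^2)`. Targets
#' with fewer than two unmasked subjects get dispersion 0 and the mean of
#' whatever values exist.
#'
#' @param cprime Adjusted count matrix.
#' @param f Size factors, one per subject.
#' @return List with numeric vectors `mu` and `phi` (one per target) and
#'   `n_obs`, the unmasked subject count per target.
#' @export
mom_dispersion <- function(cprime, f) {
  stopifnot(ncol(cprime) == length(f), all(f > 0))
  z <- sweep(cprime, 2, f, "/")
  n_obs <- rowSums(!is.na(z))
  mu <- rowMeans(z, na.rm = TRUE)
  mu[n_obs == 0] <- 0
  dev2 <- (z - mu)^2
  v <- rowSums(dev2, na.rm = TRUE) / pmax(n_obs - 1, 1)
  phi <- ifelse(n_obs >= 2 & mu > 0, pmax(0, (v - mu) / mu^2), 0)
  list(mu = as.numeric(mu), phi = as.numeric(phi), n_obs = n_obs)
}

#' Shrink per-target dispersions toward a common value
#'
#' Each raw dispersion is replaced by the convex combination
#' `(1 - delta) * phi + delta * xi`, where the weight `delta` is the
#' ratio of the squared deviation from the mean scaled by `1/(J-1)` to
#' the squared deviation from `xi` scaled by `1/(J-2)`, clamped to
#' [0, 1]. Two readings of the shrinkage target are provided:
#'
#' * `"mean"` (default): `xi` is the arithmetic mean of the raw
#'   dispersions — the stationary point of the squared-distance
#'   criterion. `delta` then equals `(J-2)/(J-1)`, i.e. near-complete
#'   shrinkage to a single pool-wide dispersion, the appropriate
#'   small-sample behavior when per-target moment estimates are noise
#'   dominated.
#' * `"min-derivative"`: `xi` minimizes the signed derivative
#'   `d/dxi { 1 / sum_j (phi_j - xi)^2 }`, with closed form
#'   `mean(phi) + sd_pop(phi)/sqrt(3)`; `delta` is then about 3/4, so a
#'   quarter of the per-target signal is retained and the common value
#'   is mildly conservative.
#'
#' The two behave almost identically on well-behaved pools; see the
#' package vignette for the sensitivity comparison. When all raw
#' dispersions coincide the weight is 1 and shrinkage is a no-op under
#' either reading.
#'
#' @param phi Raw per-target dispersions (length >= 3).
#' @param target Shrinkage-target rule, `"mean"` or `"min-derivative"`.
#' @return List with `phi_shrunk`, `delta`, and `xi`.
#' @export
shrink_dispersion <- function(phi, target = c("mean", "min-derivative")) {
  target <- match.arg(target)
  J <- length(phi)
  if (J < 3) stop("dispersion shrinkage needs at least 3 targets")
  ss_mean <- sum((phi - mean(phi))^2)
  xi <- if (target == "mean") {
    mean(phi)
  } else {
    # argmin_xi of 2*sum(phi - xi)/S(xi)^2: n*S = 4*T^2 at xi = mean + t,
    # T = -n t, S = ss_mean + n t^2  =>  t = sqrt(ss_mean/J) / sqrt(3)
    mean(phi) + sqrt(ss_mean / J) / sqrt(3)
  }
  ss_xi <- sum((phi - xi)^2)
  if (ss_xi == 0) {
    delta <- 1
  } else {
    delta <- (ss_mean / (J - 1)) / (ss_xi / (J - 2))
    delta <- min(1, max(0, delta))
  }
  list(phi_shrunk = (1 - delta) * phi + delta * xi, delta = delta, xi = xi)
}

## Grid cross-check for the shrinkage target: numerical argmin of the
## derivative of 1/sum((phi - xi)^2).
xi_grid <- function(phi, n = 20001L) {
  grid <- seq(min(phi), max(phi) + stats::sd(phi), length.out = n)
  obj <- function(xi) 2 * sum(phi - xi) / sum((phi - xi)^2)^2
  grid[which.min(vapply(grid, obj, numeric(1)))]
}

#' Maximum-likelihood copy-state update
#'
#' Assigns each subject-target cell the copy state from the grid that
#' maximizes the negative binomial likelihood with mean
#' `f_i * s * mu_j` and dispersion `phi_j / f_i`. Ties prefer the diploid
#' state, then the state nearest 1. Targets with zero estimated mean are
#' returned as `NA` (not callable).
#'
#' @param counts Count matrix (targets x subjects).
#' @param f Size factors.
#' @param mu Per-target diploid means.
#' @param phi Per-target (shrunken) dispersions.
#' @param states Copy-state grid; 0 is excluded by construction (use a
#'   small positive value such as 0.001 for homozygous deletions).
#' @return List with `states` (matrix) and `loglik` (matrix of the
#'   winning log-likelihoods).
#' @export
update_states <- function(counts, f, mu, phi,
                          states = c(0.001, 0.5, 1, 1.5, 2)) {
  stopifnot(ncol(counts) == length(f), nrow(counts) == length(mu),
            nrow(counts) == length(phi), all(states > 0))
  C <- unclass(counts)
  base_mean <- outer(mu, f)              # f_i * mu_j
  disp <- outer(phi, 1 / f)              # phi_j / f_i
  # evaluate in tie-preference order: diploid first, then nearest 1
  ord <- order(states != 1, abs(states - 1))
  best_ll <- matrix(-Inf, nrow(C), ncol(C))
  best_s <- matrix(NA_real_, nrow(C), ncol(C))
  callable <- mu > 0
  for (s in states[ord]) {
    ll <- matrix(nb_loglik(C, base_mean * s, disp), nrow(C), ncol(C))
    take <- ll > best_ll & callable
    best_s[take] <- s
    best_ll[take] <- ll[take]
  }
  best_ll[!callable, ] <- NA_real_
  dimnames(best_s) <- dimnames(counts)
  list(states = best_s, loglik = best_ll)
}

#' Exact negative binomial p-value for the diploid state
#'
#' Doubled minimum tail probability of the observed count under the
#' diploid model `NB(f * mu, phi / f)`:
#' `min(1, 2 * min(Pr(C <= c), Pr(C >= c)))`.
#'
#' @param counts Counts (vector or matrix).
#' @param f Size factors (recycled along columns for a matrix).
#' @param mu Per-target diploid means (recycled along rows).
#' @param phi Per-target dispersions.
#' @return p-values in [0, 1], same shape as `counts`; `NA` where `mu`
#'   is 0.
#' @export
diploid_pvalue <- function(counts, f, mu, phi) {
  C <- unclass(counts)
  if (is.matrix(C)) {
    m <- outer(mu, f)
    d <- outer(phi, 1 / f)
  } else {
    m <- f * mu
    d <- phi / f
  }
  lo <- nb_cdf(C, m, d, lower.tail = TRUE)        # Pr(C <= c)
  hi <- nb_cdf(C - 1, m, d, lower.tail = FALSE)   # Pr(C >= c)
  p <- pmin(1, 2 * pmin(lo, hi))
  p[m <= 0] <- NA_real_
  if (is.matrix(C)) p <- matrix(p, nrow(C), ncol(C), dimnames = dimnames(C))
  p
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of a p-value vector
#' (delegates to [stats::p.adjust()]); `NA`s are preserved.
#'
#' @param p p-values in [0, 1].
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}
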