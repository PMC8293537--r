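#' Random baseline capture simplex
#'
#' Draws per-target capture probabilities from a symmetric Dirichlet,
#' i.e. independent Gamma(concentration) variates normalized to sum to
#' one. Small concentrations give the heavy right tail typical of exome
#' captures; the default 1.5 matches the median-to-mean count ratio
#' (about 0.78) seen in real multiplexed exome pools.
#'
#' @param J Number of targets.
#' @param concentration Symmetric Dirichlet concentration (> 0).
#' @param seed Optional integer seed.
#' @return Numeric vector of length `J`, strictly positive, summing to 1.
#' @export
random_simplex <- function(J, concentration = 1.5, seed = NULL) {
  if (J < 1) stop("J must be >= 1")
  stopifnot(concentration > 0)
  if (!is.null(seed)) set.seed(seed)
  if (J == 1) return(1)
  g <- stats::rgamma(J, shape = concentration)
  # guard against underflow to exact zero at tiny concentrations
  g <- pmax(g, .Machine$double.xmin)
  g / sum(g)
}

#' Draw per-subject sequencing depths
#'
#' Total molecules per subject are uniform on a +/- `window` band around
#' the nominal depth (30% by default, so a nominal 10 million molecules
#' yields 7 to 13 million), rounded to integers.
#'
#' @param I Number of subjects.
#' @param depth Nominal molecules per subject (> 0).
#' @param window Half-width of the uniform band as a fraction of `depth`;
#'   0 makes every subject exactly `depth`.
#' @param seed Optional integer seed.
#' @return Numeric vector of `I` integer-valued depths.
#' @export
draw_depths <- function(I, depth, window = 0.3, seed = NULL) {
  stopifnot(depth > 0, window >= 0, window < 1)
  if (!is.null(seed)) set.seed(seed)
  if (window == 0) return(rep(round(depth), I))
  round(stats::runif(I, (1 - window) * depth, (1 + window) * depth))
}

#' Draw true copy states
#'
#' Each (subject, target) cell is independently diploid (state 1) with
#' probability `1 - variant_prob`; otherwise one of the non-diploid
#' states is selected uniformly. Defaults follow a total variant
#' probability of 1/1000 split equally over homozygous deletion (0),
#' heterozygous deletion (0.5), and duplications (1.5, 2).
#'
#' @param I Number of subjects.
#' @param J Number of targets.
#' @param variant_prob Total probability of a non-diploid state per cell.
#' @param states Non-diploid copy-state multipliers.
#' @param seed Optional integer seed.
#' @return Numeric matrix, targets in rows, subjects in columns.
#' @export
draw_states <- function(I, J, variant_prob = 1/1000,
                        states = c(0, 0.5, 1.5, 2), seed = NULL) {
  stopifnot(variant_prob >= 0, variant_prob <= 1)
  states <- setdiff(states, 1)
  if (!length(states) && variant_prob > 0)
    stop("no non-diploid state available while variant_prob > 0")
  if (!is.null(seed)) set.seed(seed)
  if (variant_prob == 0) return(matrix(1, nrow = J, ncol = I))
  cells <- sample(c(1, states), size = as.double(I) * J, replace = TRUE,
                  prob = c(1 - variant_prob,
                           rep(variant_prob / length(states), length(states))))
  matrix(cells, nrow = J, ncol = I)
}

#' Simulate a multiplexed-capture pool
#'
#' Models targeted capture as a multinomial process: every captured
#' molecule is one trial whose outcome is a target. Each subject's
#' outcome distribution is the shared baseline simplex re-weighted by
#' that subject's copy states and renormalized; counts are then drawn
#' multinomially with the subject's total depth as the number of trials,
#' so row sums equal realized depths exactly.
#'
#' @param subjects Pool size (>= 2).
#' @param targets Number of targets (ignored when `simplex` is given).
#' @param depth Nominal molecules per subject.
#' @param variant_prob Total per-cell probability of a non-diploid state.
#' @param states Non-diploid copy-state multipliers (see [draw_states()]).
#' @param simplex Optional explicit baseline capture simplex; defaults to
#'   [random_simplex()] with `concentration`.
#' @param concentration Concentration for the random simplex.
#' @param depth_window Half-width of the uniform depth band.
#' @param state_matrix Optional explicit truth matrix (targets x
#'   subjects) overriding the random state draw, e.g. to place variants
#'   at chosen exons.
#' @param seed Optional integer seed governing the whole pool.
#' @return A `cnv_pool`: list with `counts` (a [cnv_counts()] matrix),
#'   `states` (true copy-state matrix), `depths`, `simplex`, `seed`, and
#'   the generating parameters.
#' @export
simulate_pool <- function(subjects = 16, targets = 20000, depth = 4.5e6,
                          variant_prob = 1/1000, states = c(0, 0.5, 1.5, 2),
                          simplex = NULL, concentration = 1.5,
                          depth_window = 0.3, state_matrix = NULL,
                          seed = NULL) {
  if (subjects < 2) stop("a pool needs at least 2 subjects")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(simplex)) {
    simplex <- random_simplex(targets, concentration)
  } else {
    if (abs(sum(simplex) - 1) > 1e-12 || any(simplex <= 0))
      stop("simplex must be strictly positive and sum to 1")
    targets <- length(simplex)
  }
  n_i <- draw_depths(subjects, depth, window = depth_window)
  S <- if (is.null(state_matrix)) {
    draw_states(subjects, targets, variant_prob, states)
  } else {
    stopifnot(nrow(state_matrix) == targets,
              ncol(state_matrix) == subjects)
    unname(as.matrix(state_matrix))
  }
  C <- matrix(0L, nrow = targets, ncol = subjects)
  for (i in seq_len(subjects)) {
    w <- simplex * S[, i]
    tot <- sum(w)
    if (tot <= 0) stop("subject ", i, " has all-zero copy states")
    C[, i] <- stats::rmultinom(1, size = n_i[i], prob = w / tot)[, 1]
  }
  counts <- cnv_counts(C, subjects = sprintf("S%02d", seq_len(subjects)))
  dimnames(S) <- dimnames(counts)
  structure(list(counts = counts, states = S, depths = n_i,
                 simplex = simplex, seed = seed,
                 params = list(subjects = subjects, targets = targets,
                               depth = depth, variant_prob = variant_prob,
                               states = states,
                               concentration = concentration,
                               depth_window = depth_window)),
            class = "cnv_pool")
}

#' @export
print.cnv_pool <- function(x, ...) {
  nv <- sum(x$states != 1)
  cat(sprintf(
    "cnv_pool: %d subjects x %d targets, depth ~%s molecules/subject\n",
    ncol(x$counts), nrow(x$counts), format(x$params$depth, big.mark = ",")))
  cat(sprintf("  %d non-diploid (subject, target) cells (prior %.4g)\n",
              nv, x$params$variant_prob))
  invisible(x)
}

#' Write the true copy-state matrix to TSV
#' @param pool A `cnv_pool` or a bare states matrix with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_states <- function(pool, path) {
  S <- if (inherits(pool, "cnv_pool")) pool$states else pool
  df <- data.frame(target_id = rownames(S), S, check.names = FALSE,
                   stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#poolcnv-states-v1", con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a true copy-state matrix from TSV
#' @param path Path written by [write_states()].
#' @return Numeric matrix, targets in rows, subjects in columns.
#' @export
read_states <- function(path) {
  first <- readLines(path, n = 1L)
  skip <- if (startsWith(first, "#")) 1L else 0L
  df <- utils::read.table(path, header = TRUE, sep = "\t", skip = skip,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, setdiff(names(df), "target_id"), drop = FALSE])
  rownames(m) <- df$target_id
  m
}
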