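#' Call copy-number variants from a multiplexed-capture count matrix
#'
#' Fits the shared negative binomial read-depth model
#' `C_ij ~ NB(f_i * s_ij * mu_j, phi_j / f_i)` by iterating, from an
#' all-diploid start: (1) copy-state adjustment of the counts, (2)
#' median-of-ratios size factors over cells with adjusted count above
#' `min_count`, (3) method-of-moments per-target means and dispersions,
#' (4) shrinkage of the dispersions toward their common mean, (5)
#' maximum-likelihood copy-state assignment over a discrete grid. The
#' loop stops when the number of changed states falls to
#' `change_threshold` or after `max_iter` iterations. Afterwards each
#' cell receives a p-value for the diploid state, Benjamini-Hochberg
#' adjusted jointly across the pool; calls are cells with adjusted
#' p below `alpha` and a non-diploid state. The procedure is
#' deterministic.
#'
#' @param counts A [cnv_counts()] matrix (or bare integer matrix,
#'   targets x subjects) with at least two subjects.
#' @param alpha Adjusted-p call threshold.
#' @param states Copy-state grid searched at each cell; the default uses
#'   0.001 (not 0) for homozygous deletions so that adjustment by the
#'   state stays defined.
#' @param max_iter Maximum number of model iterations.
#' @param change_threshold Stop once no more than this many states change
#'   in an iteration.
#' @param min_count Subset threshold for the size-factor step.
#' @param p_method `"tail"` (default) gives the doubled-min-tail exact
#'   negative binomial p-value under the diploid model; `"posterior"`
#'   gives one minus the normalized likelihood of the diploid state
#'   across the grid.
#' @param shrink_target Shrinkage-target rule passed to
#'   [shrink_dispersion()].
#' @param verbose Print per-iteration progress.
#' @return A `cnvcall` object with components `calls` (long data frame:
#'   subject, chrom, start, end, target_id, state, p, p_adj, called),
#'   `variants` (merged contiguous flagged exons per subject), `state`,
#'   `p`, `p_adj` matrices, `model` (size factors, means, raw and
#'   shrunken dispersions, shrinkage weight and target), `trace`,
#'   `iterations`, `converged`, plus the inputs needed by the methods.
#' @seealso [simulate_pool()], [cnv_confusion()]
#' @export
cnv_call <- function(counts, alpha = 0.05,
                     states = c(0.001, 0.5, 1, 1.5, 2),
                     max_iter = 40L, change_threshold = 0L,
                     min_count = 10, p_method = c("tail", "posterior"),
                     shrink_target = c("mean", "min-derivative"),
                     verbose = FALSE) {
  p_method <- match.arg(p_method)
  shrink_target <- match.arg(shrink_target)
  if (!inherits(counts, "cnv_counts")) counts <- cnv_counts(counts)
  if (ncol(counts) < 2)
    stop("copy-state estimation needs at least 2 subjects ",
         "(no between-sample information in a single subject)")
  if (!1 %in% states) stop("the state grid must contain the diploid state 1")
  tgt <- targets(counts)

  zero <- rowSums(counts) == 0
  if (any(zero))
    warning(sum(zero), " all-zero target row(s) dropped from calling")
  C <- unclass(counts)[!zero, , drop = FALSE]
  J <- nrow(C); I <- ncol(C)

  s <- matrix(1, J, I, dimnames = dimnames(C))
  trace <- data.frame(iteration = integer(), n_changed = integer(),
                      delta = numeric(), xi = numeric())
  converged <- FALSE
  f <- NULL; mu <- NULL; phi <- NULL; shr <- NULL
  for (it in seq_len(max_iter)) {
    cp <- adjusted_counts(C, s)
    f <- size_factors(cp, min_count = min_count)
    mom <- mom_dispersion(cp, f)
    mu <- mom$mu; phi <- mom$phi
    shr <- shrink_dispersion(phi, target = shrink_target)
    up <- update_states(C, f, mu, shr$phi_shrunk, states = states)
    ok <- !is.na(up$states) & !is.na(s)
    n_changed <- sum(up$states[ok] != s[ok])
    s_new <- up$states
    s_new[is.na(s_new)] <- 1  # non-callable cells stay on the diploid scale
    trace <- rbind(trace, data.frame(iteration = it, n_changed = n_changed,
                                     delta = shr$delta, xi = shr$xi))
    if (verbose)
      message(sprintf("iteration %d: %d state change(s)", it, n_changed))
    s <- s_new
    if (n_changed <= change_threshold) { converged <- TRUE; break }
  }

  callable <- mu > 0
  s[!callable, ] <- NA_real_

  if (p_method == "tail") {
    p <- diploid_pvalue(C, f, mu, shr$phi_shrunk)
  } else {
    p <- posterior_pvalue(C, f, mu, shr$phi_shrunk, states)
  }
  p_adj <- matrix(bh_adjust(as.vector(p)), J, I, dimnames = dimnames(C))
  called <- !is.na(p_adj) & p_adj < alpha & !is.na(s) & s != 1

  kept <- tgt[!zero, , drop = FALSE]
  calls <- data.frame(
    subject = rep(colnames(C), each = J),
    chrom = rep(kept$chrom, I),
    start = rep(kept$start, I),
    end = rep(kept$end, I),
    target_id = rep(kept$target_id, I),
    state = as.vector(s),
    p = as.vector(p),
    p_adj = as.vector(p_adj),
    called = as.vector(called),
    stringsAsFactors = FALSE
  )

  fit <- structure(list(
    calls = calls,
    variants = merge_variants(calls, kept),
    state = s, p = p, p_adj = p_adj, called = called,
    model = list(f = f, mu = mu, phi_raw = phi,
                 phi_shrunk = shr$phi_shrunk, delta = shr$delta,
                 xi = shr$xi),
    trace = trace, iterations = nrow(trace), converged = converged,
    counts = C, targets = kept, dropped = tgt$target_id[zero],
    alpha = alpha, states = states, p_method = p_method
  ), class = "cnvcall")
  fit
}

## Pr(s != 1) from the normalized 5-state likelihood (uniform prior)
posterior_pvalue <- function(C, f, mu, phi, states) {
  base_mean <- outer(mu, f)
  disp <- outer(phi, 1 / f)
  ll <- lapply(states, function(s)
    matrix(nb_loglik(C, base_mean * s, disp), nrow(C), ncol(C)))
  mx <- Reduce(pmax, ll)
  tot <- Reduce(`+`, lapply(ll, function(m) exp(m - mx)))
  p1 <- exp(ll[[which(states == 1)]] - mx) / tot
  p <- p1  # small Pr(diploid) -> strong evidence against the diploid state
  p[mu <= 0, ] <- NA_real_
  dimnames(p) <- dimnames(C)
  p
}

## Merge contiguous flagged exons (same subject, same chrom, adjacent in
## target sort order, same direction) into variant records for reporting.
merge_variants <- function(calls, kept) {
  empty <- data.frame(subject = character(), chrom = character(),
                      start = integer(), end = integer(),
                      n_exons = integer(), direction = character(),
                      mean_state = numeric(), stringsAsFactors = FALSE)
  flagged <- calls[calls$called %in% TRUE, , drop = FALSE]
  if (!nrow(flagged)) return(empty)
  row_of <- match(flagged$target_id, kept$target_id)
  dir <- ifelse(flagged$state > 1, "dup", "del")
  key <- paste(flagged$subject, flagged$chrom, dir)
  o <- order(key, row_of)
  flagged <- flagged[o, ]; row_of <- row_of[o]; dir <- dir[o]; key <- key[o]
  new_run <- c(TRUE, key[-1] != key[-length(key)] |
                 diff(row_of) != 1L)
  run <- cumsum(new_run)
  do.call(rbind, lapply(split(seq_along(run), run), function(ix) {
    b <- flagged[ix, ]
    data.frame(subject = b$subject[1], chrom = b$chrom[1],
               start = min(b$start), end = max(b$end),
               n_exons = nrow(b),
               direction = if (b$state[1] > 1) "dup" else "del",
               mean_state = mean(b$state), stringsAsFactors = FALSE)
  }))
}

#' Write the per-exon call table to TSV
#' @param fit A `cnvcall` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calls <- function(fit, path) {
  stopifnot(inherits(fit, "cnvcall"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#poolcnv-calls-v1", con)
  utils::write.table(fit$calls, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a per-exon call table from TSV
#' @param path Path written by [write_calls()].
#' @return The calls data frame.
#' @export
read_calls <- function(path) {
  first <- readLines(path, n = 1L)
  skip <- if (startsWith(first, "#")) 1L else 0L
  df <- utils::read.table(path, header = TRUE, sep = "\t", skip = skip,
                          check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("subject", "target_id", "state", "p_adj", "called")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("calls TSV missing column(s): ", paste(miss, collapse = ", "))
  df
}
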