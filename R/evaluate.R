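#' Exon-level confusion summary against known copy states
#'
#' Scores a call set against a truth copy-state matrix at the
#' (subject, exon) level, optionally restricted to a direction stratum.
#' A pair is a predicted positive when it is flagged in the stratum's
#' direction (`DUP`: state > 1, `DEL`: state < 1, `ALL`: any non-diploid
#' call); the true condition is a truth state on the same side of 1
#' (`ALL`: any non-diploid truth). A true positive additionally requires
#' the called direction to match the true direction; a call in the wrong
#' direction scores as a false positive. Pairs with missing calls and
#' targets in `exclude` are omitted from the evaluation.
#'
#' Zero-denominator conventions: FDR is 0 with no positives, TPR is `NA`
#' with no true variants, MCC is 0 when any marginal is empty.
#'
#' @param calls A `cnvcall` fit, or a calls data frame with columns
#'   `subject`, `target_id`, `state`, `called`.
#' @param truth Truth copy-state matrix with target rownames and subject
#'   colnames (e.g. `pool$states`), or a `cnv_pool`.
#' @param stratum One or more of `"ALL"`, `"DUP"`, `"DEL"`.
#' @param exclude Optional character vector of target ids to omit (e.g.
#'   targets overlapping repetitive or low-complexity regions).
#' @return Data frame, one row per stratum: TP, FP, TN, FN, MCC, TPR,
#'   FDR, PPV, BalAcc, and `n` (evaluated pairs).
#' @export
cnv_confusion <- function(calls, truth, stratum = c("ALL", "DUP", "DEL"),
                          exclude = NULL) {
  stratum <- match.arg(stratum, several.ok = TRUE)
  if (inherits(calls, "cnvcall")) calls <- calls$calls
  if (inherits(truth, "cnv_pool")) truth <- truth$states
  need <- c("subject", "target_id", "state", "called")
  miss <- setdiff(need, names(calls))
  if (length(miss))
    stop("calls missing column(s): ", paste(miss, collapse = ", "))

  bad_t <- setdiff(unique(calls$target_id), rownames(truth))
  bad_s <- setdiff(unique(calls$subject), colnames(truth))
  if (length(bad_t) || length(bad_s))
    stop("calls/truth index mismatch; unmatched ids: ",
         paste(utils::head(c(bad_t, bad_s), 10), collapse = ", "))

  keep <- !is.na(calls$state)
  if (!is.null(exclude)) keep <- keep & !(calls$target_id %in% exclude)
  cl <- calls[keep, ]
  tr <- truth[cbind(match(cl$target_id, rownames(truth)),
                    match(cl$subject, colnames(truth)))]

  call_dir <- sign(cl$state - 1) * (cl$called %in% TRUE)
  true_dir <- sign(tr - 1)
  do.call(rbind, lapply(stratum, function(st) {
    pos <- switch(st, ALL = call_dir != 0, DUP = call_dir > 0,
                  DEL = call_dir < 0)
    cond <- switch(st, ALL = true_dir != 0, DUP = true_dir > 0,
                   DEL = true_dir < 0)
    match_dir <- call_dir == true_dir
    tp <- sum(pos & cond & match_dir)
    fp <- sum(pos) - tp
    fn <- sum(!pos & cond)
    tn <- sum(!pos & !cond)
    cbind(data.frame(stratum = st, TP = tp, FP = fp, TN = tn, FN = fn),
          confusion_metrics(tp, fp, tn, fn), data.frame(n = tp + fp + tn + fn))
  }))
}

confusion_metrics <- function(tp, fp, tn, fn) {
  tpr <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  fdr <- if (tp + fp > 0) fp / (tp + fp) else 0
  ppv <- 1 - fdr
  tnr <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  balacc <- mean(c(tpr, tnr))
  marg <- c(tp + fp, tp + fn, tn + fp, tn + fn)
  mcc <- if (any(marg == 0)) 0 else {
    (tp * tn - fp * fn) / sqrt(prod(as.numeric(marg)))
  }
  data.frame(MCC = mcc, TPR = tpr, FDR = fdr, PPV = ppv, BalAcc = balacc)
}

#' Membership tallies across labeled call sets
#'
#' Counts exon-level variants private to each call set and in each
#' intersection, stratified by direction, for 2-3 callers on a shared
#' target space (the counts drawn in a Venn diagram).
#'
#' @param ... 2-3 named data frames, each with columns `subject`,
#'   `target_id` and `direction` (`"dup"`/`"del"`), or `cnvcall` fits
#'   (their flagged exons are used).
#' @return Data frame with one row per non-empty label combination:
#'   `region`, `dup`, `del`, `total`.
#' @export
overlap_sets <- function(...) {
  sets <- list(...)
  if (length(sets) < 2 || length(sets) > 3)
    stop("supply 2 or 3 labeled call sets")
  if (is.null(names(sets)) || any(names(sets) == ""))
    stop("call sets must be named")
  sets <- lapply(sets, function(x) {
    if (inherits(x, "cnvcall")) {
      fl <- x$calls[x$calls$called %in% TRUE, ]
      data.frame(subject = fl$subject, target_id = fl$target_id,
                 direction = ifelse(fl$state > 1, "dup", "del"),
                 stringsAsFactors = FALSE)
    } else {
      stopifnot(all(c("subject", "target_id", "direction") %in% names(x)))
      x
    }
  })
  keys <- lapply(sets, function(x)
    paste(x$subject, x$target_id, x$direction, sep = "\r"))
  all_keys <- unique(unlist(keys))
  if (!length(all_keys))
    return(data.frame(region = character(), dup = integer(),
                      del = integer(), total = integer()))
  member <- vapply(keys, function(k) all_keys %in% k,
                   logical(length(all_keys)))
  member <- matrix(member, ncol = length(sets))
  region <- apply(member, 1, function(m)
    paste(names(sets)[m], collapse = "&"))
  dir <- vapply(strsplit(all_keys, "\r", fixed = TRUE), `[`, "", 3)
  out <- do.call(rbind, lapply(unique(region), function(r) {
    ix <- region == r
    data.frame(region = r, dup = sum(dir[ix] == "dup"),
               del = sum(dir[ix] == "del"), total = sum(ix),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Simulation sweep over sequencing depths
#'
#' For each nominal depth, simulates seeded pools, runs the caller and
#' scores exon-level calls against the simulated truth. Metrics are
#' computed on the confusion counts pooled over replicates (and returned
#' per replicate as well).
#'
#' @param depths Nominal molecules per subject, one value per grid point.
#' @param replicates Pools simulated per depth.
#' @param subjects,targets,variant_prob,states,concentration,depth_window
#'   Passed to [simulate_pool()].
#' @param alpha Call threshold passed to [cnv_call()].
#' @param seed Master seed; per-run seeds are derived from it.
#' @return List with `pooled` (one row per depth: depth, TP, FP, TN, FN,
#'   MCC, TPR, FDR, PPV, BalAcc) and `replicates` (the same per run).
#' @export
sweep_depths <- function(depths, replicates = 5, subjects = 16,
                         targets = 2000, variant_prob = 1/1000,
                         states = c(0, 0.5, 1.5, 2), concentration = 1.5,
                         depth_window = 0.3, alpha = 0.05, seed = 1) {
  set.seed(seed)
  run_seeds <- matrix(sample.int(.Machine$integer.max - 1,
                                 length(depths) * replicates),
                      nrow = length(depths))
  rows <- list(); pooled <- list()
  for (d in seq_along(depths)) {
    agg <- c(TP = 0, FP = 0, TN = 0, FN = 0)
    for (r in seq_len(replicates)) {
      pool <- simulate_pool(subjects = subjects, targets = targets,
                            depth = depths[d], variant_prob = variant_prob,
                            states = states, concentration = concentration,
                            depth_window = depth_window,
                            seed = run_seeds[d, r])
      fit <- withCallingHandlers(
        cnv_call(pool$counts, alpha = alpha),
        warning = function(w) {
          # uncaptured targets are routine at low sweep depths
          if (grepl("all-zero", conditionMessage(w)))
            invokeRestart("muffleWarning")
        })
      cf <- cnv_confusion(fit, pool, stratum = "ALL")
      agg <- agg + unlist(cf[1, c("TP", "FP", "TN", "FN")])
      rows[[length(rows) + 1]] <- cbind(
        data.frame(depth = depths[d], replicate = r,
                   seed = run_seeds[d, r]),
        cf[, c("TP", "FP", "TN", "FN", "MCC", "TPR", "FDR", "PPV",
               "BalAcc")])
    }
    pooled[[d]] <- cbind(
      data.frame(depth = depths[d], TP = agg["TP"], FP = agg["FP"],
                 TN = agg["TN"], FN = agg["FN"], row.names = NULL),
      confusion_metrics(agg["TP"], agg["FP"], agg["TN"], agg["FN"]))
  }
  list(pooled = do.call(rbind, pooled), replicates = do.call(rbind, rows))
}
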