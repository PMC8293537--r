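#' @export
print.cnvcall <- function(x, ...) {
  cat("Multiplexed-capture CNV call set\n")
  cat(sprintf("  pool: %d subjects x %d targets (%d dropped as all-zero)\n",
              ncol(x$counts), nrow(x$counts), length(x$dropped)))
  cat(sprintf("  iterations: %d (%s)\n", x$iterations,
              if (x$converged) "converged" else "iteration cap reached"))
  cat(sprintf("  dispersion shrinkage: delta = %.4f, xi = %.3g\n",
              x$model$delta, x$model$xi))
  n_call <- sum(x$called, na.rm = TRUE)
  cat(sprintf("  flagged exons (adjusted p < %g, state != 1): %d\n",
              x$alpha, n_call))
  cat(sprintf("  merged variants: %d\n", nrow(x$variants)))
  invisible(x)
}

#' @export
summary.cnvcall <- function(object, ...) {
  cl <- object$calls[object$calls$called %in% TRUE, ]
  per_subject <- if (nrow(cl)) {
    dir <- factor(ifelse(cl$state > 1, "dup", "del"),
                  levels = c("dup", "del"))
    tab <- table(cl$subject, dir)
    out <- data.frame(subject = rownames(tab),
                      dup = as.integer(tab[, "dup"]),
                      del = as.integer(tab[, "del"]),
                      stringsAsFactors = FALSE)
    out$total <- out$dup + out$del
    out
  } else {
    data.frame(subject = colnames(object$counts), dup = 0L, del = 0L,
               total = 0L, stringsAsFactors = FALSE)
  }
  structure(list(per_subject = per_subject,
                 size_factors = object$model$f,
                 mean_dispersion = mean(object$model$phi_shrunk),
                 delta = object$model$delta, xi = object$model$xi,
                 iterations = object$iterations,
                 converged = object$converged,
                 alpha = object$alpha,
                 n_flagged = sum(object$called, na.rm = TRUE),
                 n_variants = nrow(object$variants)),
            class = "summary.cnvcall")
}

#' @export
print.summary.cnvcall <- function(x, ...) {
  cat("Call summary\n")
  cat(sprintf("  %d flagged exons in %d merged variants (alpha = %g)\n",
              x$n_flagged, x$n_variants, x$alpha))
  cat(sprintf("  size factors: %.3f - %.3f\n",
              min(x$size_factors), max(x$size_factors)))
  cat(sprintf("  mean shrunken dispersion: %.4g (delta = %.4f, xi = %.4g)\n",
              x$mean_dispersion, x$delta, x$xi))
  cat("  calls per subject:\n")
  print(x$per_subject, row.names = FALSE)
  invisible(x)
}

#' Estimated copy-state matrix
#' @param object A `cnvcall` fit.
#' @param ... Unused.
#' @return Matrix of copy-state multipliers (1 = diploid), `NA` where a
#'   target was not callable.
#' @export
coef.cnvcall <- function(object, ...) object$state

#' @export
fitted.cnvcall <- function(object, ...) {
  s <- object$state
  s[is.na(s)] <- 1
  outer(object$model$mu, object$model$f) * s
}

#' Pearson residuals under the fitted negative binomial model
#' @param object A `cnvcall` fit.
#' @param ... Unused.
#' @return Matrix of `(c - m) / sqrt(m + phi m^2 / f)` residuals.
#' @export
residuals.cnvcall <- function(object, ...) {
  m <- fitted(object)
  disp <- outer(object$model$phi_shrunk, 1 / object$model$f)
  (object$counts - m) / sqrt(m + disp * m^2)
}

#' Plot a CNV call set
#'
#' Per-exon evidence against the diploid state (-log10 adjusted p) along
#' the target order, with flagged exons highlighted; deletions plot
#' downward-facing, duplications upward-facing triangles.
#'
#' @param x A `cnvcall` fit.
#' @param subject Subject id or column index (default: first subject).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.cnvcall <- function(x, subject = 1, ...) {
  i <- if (is.character(subject)) match(subject, colnames(x$counts)) else subject
  if (is.na(i)) stop("unknown subject: ", subject)
  y <- -log10(pmax(x$p_adj[, i], 1e-300))
  flag <- x$called[, i]
  s <- x$state[, i]
  graphics::plot(seq_along(y), y, pch = 16, cex = 0.4,
                 col = "grey60", xlab = "target index",
                 ylab = expression(-log[10] ~ "adjusted p"),
                 main = colnames(x$counts)[i], ...)
  if (any(flag, na.rm = TRUE)) {
    up <- which(flag & s > 1)
    dn <- which(flag & s < 1)
    graphics::points(up, y[up], pch = 24, bg = "firebrick", cex = 0.8)
    graphics::points(dn, y[dn], pch = 25, bg = "dodgerblue", cex = 0.8)
  }
  graphics::abline(h = -log10(x$alpha), lty = 2)
  invisible(x)
}
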