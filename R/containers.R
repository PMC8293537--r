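#' Construct a subjects-by-targets count matrix
#'
#' The universal interchange object of the package: non-negative integer
#' molecule (read-pair) counts with one row per capture target and one
#' column per subject, carrying target coordinates as metadata.
#' Coordinates are 0-based half-open (BED convention) throughout.
#'
#' @param counts Integer matrix, targets in rows, subjects in columns.
#'   Row names, if present, must match `targets$target_id`.
#' @param targets `data.frame` with columns `chrom`, `start`, `end`,
#'   `target_id`; one row per target, sorted by (chrom, start). If `NULL`,
#'   synthetic single-chromosome coordinates are generated so that row
#'   order defines adjacency.
#' @param subjects Character vector of subject identifiers; defaults to
#'   the column names of `counts` or `S01, S02, ...`.
#' @return A `cnv_counts` object: the integer matrix with a `targets`
#'   attribute.
#' @export
cnv_counts <- function(counts, targets = NULL, subjects = colnames(counts)) {
  counts <- as.matrix(counts)
  if (any(is.na(counts))) stop("counts must not contain missing values")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(counts != round(counts))) stop("counts must be integers")
  storage.mode(counts) <- "integer"
  J <- nrow(counts); I <- ncol(counts)
  if (is.null(subjects)) subjects <- sprintf("S%02d", seq_len(I))
  if (length(subjects) != I) stop("length(subjects) != ncol(counts)")
  if (anyDuplicated(subjects)) stop("duplicate subject ids")
  if (is.null(targets)) {
    targets <- data.frame(
      chrom = "chrS",
      start = (seq_len(J) - 1L) * 1000L,
      end = (seq_len(J) - 1L) * 1000L + 150L,
      target_id = if (is.null(rownames(counts))) {
        sprintf("T%05d", seq_len(J))
      } else rownames(counts),
      stringsAsFactors = FALSE
    )
  }
  targets <- validate_targets(targets)
  if (nrow(targets) != J) stop("nrow(targets) != nrow(counts)")
  dimnames(counts) <- list(targets$target_id, subjects)
  structure(counts, targets = targets, class = c("cnv_counts", "matrix", "array"))
}

#' @export
print.cnv_counts <- function(x, ...) {
  cat(sprintf("cnv_counts: %d targets x %d subjects\n", nrow(x), ncol(x)))
  cat(sprintf("  total molecules per subject: %s\n",
              paste(format(colSums(x), big.mark = ","), collapse = ", ")))
  invisible(x)
}

#' Target metadata of a count matrix
#' @param x A `cnv_counts` object.
#' @return The targets `data.frame`.
#' @export
targets <- function(x) attr(x, "targets")

validate_targets <- function(targets) {
  need <- c("chrom", "start", "end", "target_id")
  miss <- setdiff(need, names(targets))
  if (length(miss))
    stop("targets missing column(s): ", paste(miss, collapse = ", "))
  targets <- targets[, need]
  if (any(targets$end <= targets$start))
    stop("zero- or negative-length target(s): ",
         paste(targets$target_id[targets$end <= targets$start], collapse = ", "))
  dup <- targets$target_id[duplicated(targets$target_id)]
  if (length(dup)) stop("duplicate target id(s): ", paste(unique(dup), collapse = ", "))
  o <- order(targets$chrom, targets$start)
  if (any(o != seq_along(o)))
    stop("targets must be sorted by (chrom, start)")
  targets
}

COUNTS_FORMAT <- "#poolcnv-counts-v1"

#' Write a count matrix to TSV
#'
#' Columns: chrom, start, end, target_id, then one column per subject.
#' A one-line format header comment precedes the column header.
#'
#' @param x A `cnv_counts` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(x, path) {
  stopifnot(inherits(x, "cnv_counts"))
  df <- cbind(targets(x), as.data.frame(unclass(x), check.names = FALSE),
              stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(COUNTS_FORMAT, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a count matrix from TSV
#'
#' Inverse of [write_counts()]; validates structure and reports the
#' offending row/column on malformed input.
#'
#' @param path Path to a counts TSV.
#' @return A `cnv_counts` object.
#' @export
read_counts <- function(path) {
  first <- readLines(path, n = 1L)
  skip <- 0L
  if (startsWith(first, "#")) {
    if (first != COUNTS_FORMAT)
      stop("unrecognized counts format header: ", first)
    skip <- 1L
  }
  df <- utils::read.table(path, header = TRUE, sep = "\t", skip = skip,
                          check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "target_id")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("counts TSV missing column(s): ", paste(miss, collapse = ", "))
  subj <- setdiff(names(df), need)
  if (!length(subj)) stop("counts TSV has no subject columns")
  m <- as.matrix(df[, subj, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- subj[!vapply(df[subj], is.numeric, logical(1))]
    stop("non-numeric count column(s): ", paste(bad, collapse = ", "))
  }
  if (any(m != round(m))) {
    idx <- which(m != round(m), arr.ind = TRUE)[1, ]
    stop(sprintf("non-integer count at target '%s', subject '%s'",
                 df$target_id[idx[1]], subj[idx[2]]))
  }
  if (any(m < 0)) {
    idx <- which(m < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative count at target '%s', subject '%s'",
                 df$target_id[idx[1]], subj[idx[2]]))
  }
  cnv_counts(m, targets = df[, need], subjects = subj)
}

#' Read capture targets from a BED file
#'
#' BED3+ input; column 4, when present, supplies target ids, otherwise
#' ids are generated as `chrom:start-end`. Coordinates stay 0-based
#' half-open.
#'
#' @param path Path to a BED file.
#' @return A targets `data.frame` (chrom, start, end, target_id) sorted
#'   by (chrom, start).
#' @export
read_targets <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,  # back to 0-based half-open
    end = GenomicRanges::end(gr),
    target_id = if (!is.null(gr$name) && !all(is.na(gr$name))) {
      as.character(gr$name)
    } else NA_character_,
    stringsAsFactors = FALSE
  )
  auto <- is.na(df$target_id)
  df$target_id[auto] <- sprintf("%s:%d-%d", df$chrom[auto], df$start[auto],
                                df$end[auto])
  df <- df[order(df$chrom, df$start), ]
  rownames(df) <- NULL
  validate_targets(df)
}

targets_as_granges <- function(targets) {
  GenomicRanges::GRanges(
    seqnames = targets$chrom,
    ranges = IRanges::IRanges(start = targets$start + 1L, end = targets$end)
  )
}
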