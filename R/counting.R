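#' Count molecules (read pairs) per target
#'
#' Converts paired-end alignments into per-target molecule counts. A
#' molecule is the physical fragment covered by a read pair; its span on
#' the reference runs from the leftmost mate start to the rightmost mate
#' end. A molecule passes the inclusion filters when it is properly
#' paired, neither read is flagged as a duplicate, both mates are primary
#' non-supplementary alignments, and both mapping qualities are at least
#' `min_mapq`. Each passing molecule increments the count of every target
#' its span overlaps by at least one base, at most once per target.
#'
#' @param alignments Path to a coordinate-sorted BAM with an index, or to
#'   a SAM file (converted, sorted and indexed in a temporary location).
#' @param targets A targets `data.frame` (see [read_targets()]) or a path
#'   to a BED file.
#' @param min_mapq Minimum mapping quality required of both reads.
#' @return A list with `counts` (named integer vector, one per target),
#'   `targets`, and `qc` (molecules seen / failed per filter / passed).
#' @export
count_molecules <- function(alignments, targets, min_mapq = 20L) {
  if (is.character(targets)) targets <- read_targets(targets)
  targets <- validate_targets(targets)
  bam <- prepare_bam(alignments)

  hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  absent <- setdiff(unique(targets$chrom), names(hdr))
  if (length(absent))
    warning("target chromosome(s) absent from alignment header: ",
            paste(absent, collapse = ", "), "; their counts are zero")

  flag <- Rsamtools::scanBamFlag(
    isPaired = TRUE, isUnmappedQuery = FALSE, hasUnmappedMate = FALSE,
    isSecondaryAlignment = FALSE, isSupplementaryAlignment = FALSE
  )
  param <- Rsamtools::ScanBamParam(flag = flag, what = c("flag", "mapq"))
  gp <- GenomicAlignments::readGAlignmentPairs(bam, param = param)

  f1 <- S4Vectors::mcols(GenomicAlignments::first(gp))
  f2 <- S4Vectors::mcols(GenomicAlignments::second(gp))
  seen <- length(gp)

  proper <- bitwAnd(f1$flag, 0x2L) > 0L & bitwAnd(f2$flag, 0x2L) > 0L
  nondup <- bitwAnd(f1$flag, 0x400L) == 0L & bitwAnd(f2$flag, 0x400L) == 0L
  mq_ok <- !is.na(f1$mapq) & !is.na(f2$mapq) &
    f1$mapq >= min_mapq & f2$mapq >= min_mapq
  keep <- proper & nondup & mq_ok

  qc <- c(seen = seen,
          failed_proper_pair = sum(!proper),
          failed_duplicate = sum(proper & !nondup),
          failed_mapq = sum(proper & nondup & !mq_ok),
          passed = sum(keep))

  tgt_gr <- targets_as_granges(targets)
  if (any(keep)) {
    frag <- GenomicRanges::granges(gp[keep])  # span covering both mates
    n <- GenomicRanges::countOverlaps(tgt_gr, frag, minoverlap = 1L)
  } else {
    n <- integer(nrow(targets))
  }
  names(n) <- targets$target_id
  list(counts = n, targets = targets, qc = qc)
}

## Accepts .sam (converted+sorted+indexed in tempdir) or an indexed,
## coordinate-sorted .bam; anything else is an explicit error.
prepare_bam <- function(path) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    tmp <- tempfile(fileext = ".bam")
    bam <- Rsamtools::asBam(path, sub("\\.bam$", "", tmp),
                            indexDestination = FALSE)
    sorted <- Rsamtools::sortBam(bam, tempfile())
    Rsamtools::indexBam(sorted)
    return(sorted)
  }
  if (!grepl("\\.bam$", path, ignore.case = TRUE))
    stop("alignments must be a SAM or BAM file: ", path)
  idx <- paste0(path, ".bai")
  idx2 <- sub("\\.bam$", ".bai", path)
  if (!file.exists(idx) && !file.exists(idx2))
    stop("BAM has no index (.bai); coordinate-sort and index it first: ", path)
  hso <- tryCatch({
    h <- Rsamtools::scanBamHeader(path)[[1]]$text[["@HD"]]
    any(grepl("SO:coordinate", h))
  }, error = function(e) TRUE)
  if (isFALSE(hso))
    stop("BAM is not coordinate-sorted (header @HD SO): ", path)
  path
}

#' Count molecules for several subjects into a count matrix
#'
#' @param alignment_files Named character vector of SAM/BAM paths; names
#'   are subject ids.
#' @param targets Targets `data.frame` or BED path.
#' @param min_mapq Minimum mapping quality required of both reads.
#' @return A `cnv_counts` object.
#' @export
count_pool <- function(alignment_files, targets, min_mapq = 20L) {
  if (is.character(targets)) targets <- read_targets(targets)
  if (is.null(names(alignment_files)))
    names(alignment_files) <- sub("\\.(sam|bam)$", "",
                                  basename(alignment_files))
  cols <- lapply(alignment_files, function(f)
    count_molecules(f, targets, min_mapq = min_mapq)$counts)
  cnv_counts(do.call(cbind, cols), targets = targets,
             subjects = names(alignment_files))
}
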