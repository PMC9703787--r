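#' Selection parameters for mitochondrial contigs
#'
#' @param min_len minimum contig length (bp) for coverage-based selection
#'   (criterion 2); default 2,000 bp.
#' @param cov_range optional explicit coverage range `c(lo, hi)`; when NULL
#'   it is derived from the gene-hit (criterion 1) contigs.
#' @param assembler_min_contig minimum contig length emitted by the
#'   assembler (bp), recorded for provenance.
#' @return list of class `select_params`.
#' @export
select_params <- function(min_len = 2000, cov_range = NULL,
                          assembler_min_contig = 500) {
  stopifnot(min_len >= assembler_min_contig)
  if (!is.null(cov_range)) stopifnot(length(cov_range) == 2,
                                     cov_range[1] <= cov_range[2])
  structure(list(min_len = min_len, cov_range = cov_range,
                 assembler_min_contig = assembler_min_contig),
            class = "select_params")
}

#' Mean short-read mapping coverage per contig
#'
#' Maps short reads to the contigs under the package's mapping contract
#' (length fraction 0.9, similarity 0.95 by default) and records mean depth
#' as aligned bases / contig length.
#'
#' @param contigs data.frame with `id`, `sequence`.
#' @param short_reads a data.frame of reads or a list with `read1`/`read2`
#'   data.frames.
#' @param params a [map_params()] object.
#' @return data.frame with `id`, `mean_cov`.
#' @export
compute_mean_coverage <- function(contigs, short_reads,
                                  params = map_params(similarity = 0.95)) {
  contigs <- as_seq_df_keep(contigs)
  reads <- combine_reads(short_reads)
  if (nrow(reads) == 0) {
    warning("no reads supplied; all coverages are 0")
    return(data.frame(id = contigs$id, mean_cov = 0, stringsAsFactors = FALSE))
  }
  pl <- map_short_reads(reads, contigs, params)
  cov <- vapply(contigs$id, function(cid) {
    p <- pl[[cid]]
    sum(p$counts[1:4, , drop = FALSE]) / p$ref_len
  }, numeric(1))
  data.frame(id = contigs$id, mean_cov = unname(cov), stringsAsFactors = FALSE)
}

#' Select mitochondrial contigs
#'
#' Two selection criteria: (1) any contig carrying at least one
#' mitochondrial gene hit is selected regardless of length or coverage;
#' (2) contigs of at least `min_len` bp whose mean coverage falls within the
#' coverage range of the criterion-1 contigs (boundaries inclusive). An
#' explicit `cov_range` in the parameters overrides the derived range.
#'
#' @param contigs data.frame with `id`, `length` (or `sequence`),
#'   `mean_cov`, and `gene_hits` (comma-separated gene names, "" for none).
#' @param params a [select_params()] object.
#' @return the contig data.frame with `selected` flag, `reason` and the
#'   applied coverage range as attribute `cov_range`.
#' @export
select_mito_contigs <- function(contigs, params = select_params()) {
  stopifnot(is.data.frame(contigs), !is.null(contigs$mean_cov))
  if (is.null(contigs$length)) contigs$length <- nchar(contigs$sequence)
  gh <- contigs$gene_hits
  if (is.null(gh)) stop("contigs lack a gene_hits column")
  crit1 <- !is.na(gh) & gh != ""
  cov_range <- params$cov_range
  if (is.null(cov_range)) {
    if (!any(crit1))
      stop("no contig with a mitochondrial gene hit: the coverage range is ",
           "undefined; supply cov_range explicitly in select_params()")
    cov_range <- range(contigs$mean_cov[crit1])
  }
  crit2 <- contigs$length >= params$min_len &
    contigs$mean_cov >= cov_range[1] & contigs$mean_cov <= cov_range[2]
  contigs$selected <- crit1 | crit2
  contigs$reason <- ifelse(crit1, "gene_hit",
                           ifelse(crit2, "coverage_range", ""))
  attr(contigs, "cov_range") <- cov_range
  contigs
}

#' Assign copy-number classes from relative coverage
#'
#' Computes each selected contig's coverage ratio to the median coverage of
#' the selected set and assigns a copy class: `low` below `low_max`,
#' `single` up to `single_max`, and otherwise `multiple(k)` when the ratio
#' is within `mult_tol` of an integer k, else `intermediate(k, k+1)` for the
#' bracketing integers. Contigs with ratio at or above `single_max` are
#' flagged repeat-like and become eligible for multi-placement during
#' scaffolding.
#'
#' @param contigs data.frame with `mean_cov` and (optionally) `selected`.
#' @param low_max upper ratio bound of the `low` class (default 0.80).
#' @param single_max upper ratio bound of the `single` class (default 1.25).
#' @param mult_tol half-width around integer ratios for `multiple(k)`
#'   (default 0.15).
#' @return the data.frame with `cov_ratio`, `copy_class`, `repeat_like`
#'   columns; attribute `median_cov` carries the median.
#' @export
assign_copy_class <- function(contigs, low_max = 0.80, single_max = 1.25,
                              mult_tol = 0.15) {
  sel <- if (!is.null(contigs$selected)) contigs$selected else
    rep(TRUE, nrow(contigs))
  if (sum(sel) < 3) stop("need at least 3 selected contigs")
  med <- median(contigs$mean_cov[sel])
  if (med == 0) stop("median coverage is zero")
  ratio <- contigs$mean_cov / med
  cls <- character(nrow(contigs))
  for (i in seq_len(nrow(contigs))) {
    r <- ratio[i]
    cls[i] <- if (!sel[i]) NA_character_
    else if (r < low_max) "low"
    else if (r < single_max) "single"
    else {
      k <- round(r)
      if (abs(r - k) <= mult_tol && k >= 2) sprintf("multiple(%d)", k)
      else sprintf("intermediate(%d,%d)", floor(r), floor(r) + 1L)
    }
  }
  contigs$cov_ratio <- ratio
  contigs$copy_class <- cls
  contigs$repeat_like <- sel & ratio >= single_max
  attr(contigs, "median_cov") <- med
  contigs
}
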