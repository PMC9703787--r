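#' Estimate the cellular copy number of the mitogenome
#'
#' Copy number per cell = mean mapping coverage of the mitogenome divided by
#' the haploid nuclear genome coverage of the input data, the latter being
#' input bases / haploid genome size. For the published *Abies alba* inputs
#' (70.3x, 7.43 Gbp, 16.94 Gbp) this gives about 160 copies per cell.
#'
#' @param mean_mito_cov mean mapping coverage to the mitogenome (x).
#' @param input_bases total sequenced input (bp).
#' @param haploid_genome_size haploid nuclear genome size (bp).
#' @return list with `copies` (raw value) and `copies_2sf` (rounded to two
#'   significant figures for the headline report).
#' @export
estimate_copy_number <- function(mean_mito_cov, input_bases,
                                 haploid_genome_size) {
  if (any(c(mean_mito_cov, input_bases, haploid_genome_size) <= 0))
    stop("all copy-number inputs must be positive")
  raw <- mean_mito_cov / (input_bases / haploid_genome_size)
  list(copies = raw, copies_2sf = signif(raw, 2))
}

#' Pearson correlation with a two-sided p-value
#'
#' Standard product-moment correlation; the p-value comes from the t
#' transform with n - 2 degrees of freedom.
#'
#' @param xs,ys numeric vectors of equal length (n >= 3).
#' @return list with `r`, `p` and `n`.
#' @export
pearson_correlation <- function(xs, ys) {
  stopifnot(length(xs) == length(ys), length(xs) >= 3)
  if (stats::sd(xs) == 0 || stats::sd(ys) == 0)
    stop("degenerate input: zero variance")
  ct <- cor.test(xs, ys, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(xs))
}

#' Repeat proportion versus mitogenome size across genomes
#'
#' Runs the repeat finder on each genome, tabulates mitogenome size (Mbp)
#' against repeat proportion, and reports the Pearson correlation between
#' the two when at least three genomes are supplied.
#'
#' @param genomes named list: each element the sequence set of one genome
#'   (data.frame or named character vector), or a precomputed data.frame
#'   with columns `species`, `size_mbp`, `repeat_proportion`.
#' @param min_len minimum repeat length (default 24 bp, the inclusive
#'   reporting tier).
#' @param mode repeat accounting mode (see [repeat_proportion()]).
#' @return list with `table` (species, size_mbp, repeat_proportion) and,
#'   when computable, `r` and `p`.
#' @export
size_vs_repeat_table <- function(genomes, min_len = 24, mode = "union") {
  if (is.data.frame(genomes)) {
    tab <- genomes
    stopifnot(all(c("species", "size_mbp", "repeat_proportion") %in%
                    names(tab)))
  } else {
    stopifnot(length(genomes) >= 1)
    rows <- lapply(names(genomes), function(sp) {
      v <- as_seq_vector(genomes[[sp]])
      rs <- find_repeats(v, min_len = min_len)
      data.frame(species = sp, size_mbp = sum(nchar(v)) / 1e6,
                 repeat_proportion = repeat_proportion(rs, mode = mode),
                 stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
  }
  if (nrow(tab) < 3) {
    warning("fewer than 3 genomes: correlation skipped")
    return(list(table = tab, r = NA_real_, p = NA_real_))
  }
  pc <- pearson_correlation(tab$size_mbp, tab$repeat_proportion)
  list(table = tab, r = pc$r, p = pc$p)
}
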