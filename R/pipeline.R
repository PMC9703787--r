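#' Default pipeline configuration
#'
#' All stage parameters surface as named keys with their conventional
#' defaults: 2,000 bp minimum contig length for coverage-based selection,
#' long reads of at least 10 kb at 90% identity with 3 supporting reads per
#' connection, mapping at length fraction 0.9 with similarity 0.90/0.95 over
#' the two polishing passes, low-coverage threshold 5, repeat tiers of 24
#' and 50 bp, and MTPT thresholds of 50 bp and 90% identity.
#'
#' @param paths named list of input paths (contigs, coverage, gene_hits,
#'   long_reads, short_reads_1, short_reads_2, plastome, outdir).
#' @param seed integer seed for simulation subcommands.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(paths = list(), seed = 1) {
  structure(list(
    paths = paths,
    seed = as.integer(seed),
    select = list(min_len = 2000, cov_range = NULL,
                  assembler_min_contig = 500),
    copy_class = list(low_max = 0.80, single_max = 1.25, mult_tol = 0.15),
    scaffold = list(min_read_len = 10000, min_identity = 0.90,
                    min_end_overlap = 10000, min_support = 3),
    map = list(length_fraction = 0.9, similarity_pass1 = 0.90,
               similarity_pass2 = 0.95, low_cov_threshold = 5),
    repeats = list(min_len = 24, summary_min_len = 50, mode = "union"),
    mtpt = list(min_len = 50, min_identity = 0.90, merge_gap = 10)),
    class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; keys override [pipeline_config()] defaults.
#' @return a `pipeline_config` object.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  cfg <- pipeline_config()
  for (k in names(y)) {
    cfg[[k]] <- if (is.list(cfg[[k]]) && is.list(y[[k]]))
      utils::modifyList(cfg[[k]], y[[k]]) else y[[k]]
  }
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Write a simulated dataset to disk
#'
#' Thin wrapper over the synthetic-data generators: simulates a genome from
#' `sim_config(seed = config$seed)` (or a supplied `sim_config`), fragments
#' it into contigs, simulates reads, and writes contigs FASTA, coverage and
#' gene-hit TSVs, long reads FASTA, paired short reads FASTQ, molecule
#' FASTA and truth tables into `outdir`.
#'
#' @param config a `pipeline_config` (used for `seed` and `paths$outdir`).
#' @param sim a `sim_config`; defaults to `sim_config(seed = config$seed)`.
#' @param base_depth single-copy short-read depth for the coverage table.
#' @return invisible list with the truth object and the written file paths.
#' @export
simulate_cmd <- function(config, sim = NULL, base_depth = 89) {
  outdir <- config$paths$outdir %||% stop("config error: paths$outdir missing")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  sim <- sim %||% sim_config(seed = config$seed)
  truth <- simulate_mitogenome(sim)
  fr <- fragment_to_contigs(truth, base_depth = base_depth)
  lr <- simulate_long_reads(truth)
  sr <- simulate_short_reads(truth)
  p <- function(f) file.path(outdir, f)
  write_fasta(truth$molecules[, c("id", "sequence")], p("molecules.fasta"))
  write_fasta(fr$contigs[, c("id", "sequence")], p("contigs.fasta"))
  write_tsv(fr$coverage, p("coverage.tsv"))
  write_tsv(fr$contigs[, c("id", "gene_hits")], p("gene_hits.tsv"))
  write_fasta(lr[, c("id", "sequence")], p("long_reads.fasta"))
  write_fastq(sr$read1, p("short_reads_1.fastq"))
  write_fastq(sr$read2, p("short_reads_2.fastq"))
  write_tsv(truth$junctions, p("truth_junctions.tsv"))
  write_tsv(truth$repeat_placements, p("truth_repeats.tsv"))
  write_tsv(truth$mtpt_truth, p("truth_mtpts.tsv"))
  write_tsv(truth$contig_truth, p("truth_contigs.tsv"))
  files <- c("molecules.fasta", "contigs.fasta", "coverage.tsv",
             "gene_hits.tsv", "long_reads.fasta", "short_reads_1.fastq",
             "short_reads_2.fastq", "truth_junctions.tsv",
             "truth_repeats.tsv", "truth_mtpts.tsv", "truth_contigs.tsv")
  invisible(list(truth = truth, files = file.path(outdir, files)))
}

#' Run the full pipeline
#'
#' Stages in order: contig selection (gene hits + coverage range), copy
#' classification, long-read scaffolding, short-read polishing (with
#' plastome decoy when provided), repeat detection and MTPT detection, and
#' assembly statistics. Writes every stage's outputs plus a manifest with
#' md5 checksums; identical config and inputs give identical checksums.
#'
#' @param config a `pipeline_config` with `paths` naming contigs, coverage,
#'   gene_hits, long_reads, short_reads_1/short_reads_2, optionally
#'   plastome, and outdir.
#' @return the manifest data.frame (file, stage, md5), invisibly a list
#'   with all stage results.
#' @export
run_pipeline <- function(config) {
  pt <- config$paths
  need <- c("contigs", "coverage", "gene_hits", "long_reads",
            "short_reads_1", "short_reads_2", "outdir")
  for (k in need)
    if (is.null(pt[[k]])) stop("config error: missing path '", k, "'")
  for (k in setdiff(need, "outdir"))
    if (!file.exists(pt[[k]])) stop("config error: input does not exist: ",
                                    pt[[k]])
  if (!is.null(pt$plastome) && !file.exists(pt$plastome))
    stop("config error: input does not exist: ", pt$plastome)
  outdir <- pt$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(); results <- list()
  emit <- function(file, stage) {
    manifest[[length(manifest) + 1]] <<- data.frame(
      file = basename(file), stage = stage,
      md5 = unname(tools::md5sum(file)), stringsAsFactors = FALSE)
  }
  message("[select] reading inputs")
  contigs <- read_fasta(pt$contigs)
  cov <- read_tsv(pt$coverage)
  gh <- read_tsv(pt$gene_hits)
  contigs$length <- nchar(contigs$sequence)
  contigs$mean_cov <- cov$mean_cov[match(contigs$id, cov$id)]
  contigs$gene_hits <- gh$gene_hits[match(contigs$id, gh$id)]
  contigs$gene_hits[is.na(contigs$gene_hits)] <- ""
  sp <- config$select
  sel <- select_mito_contigs(contigs, select_params(sp$min_len,
                                                    sp$cov_range,
                                                    sp$assembler_min_contig))
  cc <- config$copy_class
  sel <- assign_copy_class(sel, cc$low_max, cc$single_max, cc$mult_tol)
  sel_out <- sel[, c("id", "length", "mean_cov", "cov_ratio", "copy_class",
                     "repeat_like", "selected", "reason")]
  f <- file.path(outdir, "selection.tsv")
  write_tsv(sel_out, f); emit(f, "select")
  results$selection <- sel

  message("[scaffold] building scaffolds from long reads")
  long_reads <- read_fasta(pt$long_reads)
  keep <- sel[sel$selected, , drop = FALSE]
  scp <- config$scaffold
  sset <- build_scaffolds(keep, long_reads,
                          scaffold_params(min_read_len = scp$min_read_len,
                                          min_identity = scp$min_identity,
                                          min_end_overlap = scp$min_end_overlap,
                                          min_support = scp$min_support))
  scf_df <- data.frame(
    id = vapply(sset$scaffolds, `[[`, character(1), "id"),
    sequence = vapply(sset$scaffolds, `[[`, character(1), "sequence"),
    stringsAsFactors = FALSE)
  f <- file.path(outdir, "scaffolds.fasta")
  write_fasta(scf_df, f); emit(f, "scaffold")
  plac <- do.call(rbind, lapply(sset$scaffolds, function(s) {
    d <- s$placements; d$scaffold <- s$id; d
  }))
  f <- file.path(outdir, "placements.tsv")
  write_tsv(plac[, c("scaffold", "contig", "orientation", "start", "end")], f)
  emit(f, "scaffold")
  ev_agg <- aggregate_evidence(sset$evidence)
  f <- file.path(outdir, "evidence.tsv")
  write_tsv(ev_agg, f); emit(f, "scaffold")
  f <- file.path(outdir, "adjacency_report.tsv")
  write_tsv(sset$adjacency_report, f); emit(f, "scaffold")
  results$scaffolds <- sset

  message("[polish] two-pass short-read polishing")
  sr1 <- read_fastq(pt$short_reads_1)
  sr2 <- read_fastq(pt$short_reads_2)
  plastome <- if (!is.null(pt$plastome)) read_fasta(pt$plastome) else NULL
  mp <- config$map
  pol <- polish_scaffolds(sset, list(sr1, sr2), plastome,
                          low_cov_threshold = mp$low_cov_threshold,
                          similarities = c(mp$similarity_pass1,
                                           mp$similarity_pass2),
                          length_fraction = mp$length_fraction)
  f <- file.path(outdir, "scaffolds_polished.fasta")
  write_fasta(pol$scaffolds, f); emit(f, "polish")
  f <- file.path(outdir, "polish_changes.tsv")
  write_tsv(pol$changes, f); emit(f, "polish")
  if (nrow(pol$low_coverage)) {
    f <- file.path(outdir, "low_coverage.bed")
    write_bed(pol$low_coverage, f); emit(f, "polish")
  }
  results$polished <- pol

  message("[repeats] repeat and MTPT detection")
  rp <- config$repeats
  rs <- find_repeats(pol$scaffolds, min_len = rp$min_len)
  fam <- merge(rs$families,
               aggregate(list(coords = paste(rs$copies$seq_id,
                                             rs$copies$start,
                                             rs$copies$end, sep = ":")),
                         by = list(family_id = rs$copies$family_id),
                         FUN = paste, collapse = ","),
               by = "family_id")
  f <- file.path(outdir, "repeat_families.tsv")
  write_tsv(fam, f); emit(f, "repeats")
  bed <- data.frame(seq_id = rs$copies$seq_id, start = rs$copies$start,
                    end = rs$copies$end, name = rs$copies$family_id,
                    strand = rs$copies$strand)
  f <- file.path(outdir, "repeats.bed")
  write_bed(bed, f); emit(f, "repeats")
  summ <- repeat_summary(rs, min_len = rp$summary_min_len)
  f <- file.path(outdir, "repeat_size_histogram.tsv")
  write_tsv(summ$size_histogram, f); emit(f, "repeats")
  results$repeats <- rs
  results$repeat_proportion <- repeat_proportion(rs, mode = rp$mode)

  if (!is.null(plastome)) {
    mq <- config$mtpt
    mt <- find_mtpts(pol$scaffolds, plastome, min_len = mq$min_len,
                     min_identity = mq$min_identity,
                     merge_gap = mq$merge_gap)
    if (nrow(mt$regions)) {
      f <- file.path(outdir, "mtpt.bed")
      write_bed(data.frame(seq_id = mt$regions$seq_id,
                           start = mt$regions$start, end = mt$regions$end,
                           name = sprintf("mtpt_%d",
                                          seq_len(nrow(mt$regions))),
                           strand = mt$regions$strand), f)
      emit(f, "mtpt")
    }
    f <- file.path(outdir, "mtpt.tsv")
    write_tsv(mt$regions, f); emit(f, "mtpt")
    results$mtpt <- mt
  }

  message("[stats] assembly statistics")
  st <- assembly_stats(pol$scaffolds)
  stats_df <- data.frame(
    metric = c("n_scaffolds", "total_len", "largest_len", "n50",
               "gc_percent", "n_gap_bases", "repeat_proportion"),
    value = c(st$n_seqs, st$total_len, st$largest_len, st$n50,
              round(100 * st$gc_fraction, 2), st$n_gap_bases,
              round(results$repeat_proportion, 4)))
  f <- file.path(outdir, "assembly_stats.tsv")
  write_tsv(stats_df, f); emit(f, "stats")
  results$stats <- st

  manifest <- do.call(rbind, manifest)
  write_tsv(manifest, file.path(outdir, "manifest.tsv"))
  results$manifest <- manifest
  invisible(results)
}

# aggregate raw junction evidence rows per oriented connection
aggregate_evidence <- function(EV) {
  if (nrow(EV) == 0)
    return(data.frame(from = character(0), s1 = character(0),
                      to = character(0), s2 = character(0),
                      support = integer(0), best_read = character(0)))
  key <- paste(EV$from, EV$s1, EV$to, EV$s2, sep = "\r")
  rows <- lapply(split(EV, key), function(d) {
    data.frame(from = d$from[1], s1 = d$s1[1], to = d$to[1], s2 = d$s2[1],
               support = length(unique(d$read)),
               best_read = d$read[which.max(d$jspan)],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$support, out$from, out$to), , drop = FALSE]
  rownames(out) <- NULL
  out
}
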