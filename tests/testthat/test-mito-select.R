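test_that("mean mapping coverage recovers simulated depth and pools repeat copies", {
  cfg <- sim_config(seed = 41, unique_len_range = c(4000, 7000),
                    molecules = list(
                      list(id = "m1", circular = TRUE, copies = 1,
                           layout = c("U1", "R1", "U2", "R1"))),
                    repeat_len_mixture = list(p_bulk = 0,
                                              bulk_range = c(50, 200),
                                              tail_range = c(3000, 4000)))
  tr <- simulate_mitogenome(cfg)
  fr <- fragment_to_contigs(tr, noise_cv = 0)
  sr <- simulate_short_reads(tr, list(depth = 30))
  cov <- compute_mean_coverage(fr$contigs, sr)
  uni <- cov$mean_cov[cov$id != "R1"]
  expect_true(all(abs(uni - 30) < 0.15 * 30))
  ratio <- cov$mean_cov[cov$id == "R1"] / mean(uni)
  expect_lt(abs(ratio - 2), 0.3)

  expect_warning(
    z <- compute_mean_coverage(fr$contigs,
                               data.frame(id = character(0),
                                          sequence = character(0))),
    "no reads")
  expect_true(all(z$mean_cov == 0))
})

test_that("contig selection applies the gene-hit and coverage-range criteria", {
  contigs <- data.frame(
    id = c("c1", "c2", "c3", "c4", "c5"),
    length = c(5000, 2500, 1900, 3000, 4000),
    mean_cov = c(32, 100, 100, 139, 150),
    gene_hits = c("cox1", "", "", "nad5", "cox1"),
    stringsAsFactors = FALSE)
  sel <- select_mito_contigs(contigs)
  # the gene-hit contigs define the coverage range
  expect_equal(attr(sel, "cov_range"), c(32, 150))
  # 2,500 bp at 100x without a hit: selected by coverage
  expect_true(sel$selected[sel$id == "c2"])
  # 1,900 bp is below the 2,000 bp length threshold
  expect_false(sel$selected[sel$id == "c3"])
  # boundary coverages are inclusive
  expect_true(sel$selected[sel$id == "c1"])
  expect_true(sel$selected[sel$id == "c4"])
  # under the published range [32, 139], a gene hit selects a contig whose
  # 150x coverage lies outside the range
  fixed <- select_mito_contigs(contigs,
                               select_params(cov_range = c(32, 139)))
  expect_true(fixed$selected[fixed$id == "c5"])
  expect_equal(fixed$reason[fixed$id == "c5"], "gene_hit")

  # idempotent and order-invariant
  again <- select_mito_contigs(sel)
  expect_equal(again$selected, sel$selected)
  perm <- select_mito_contigs(contigs[c(4, 2, 5, 1, 3), ])
  expect_equal(perm$selected[order(perm$id)], sel$selected[order(sel$id)])

  # widening the range never deselects
  wide <- select_mito_contigs(contigs,
                              select_params(cov_range = c(10, 400)))
  expect_true(all(wide$selected[sel$selected]))

  nohit <- contigs; nohit$gene_hits <- ""
  expect_error(select_mito_contigs(nohit), "cov_range")
})

test_that("copy classes follow the ratio bands around the median coverage", {
  contigs <- data.frame(
    id = sprintf("c%d", 1:7),
    length = rep(5000, 7),
    mean_cov = c(89, 89, 89, 204, 178, 50, 110),
    gene_hits = "cox1", selected = TRUE,
    stringsAsFactors = FALSE)
  cc <- assign_copy_class(contigs)
  expect_equal(attr(cc, "median_cov"), 89)
  expect_equal(cc$copy_class[cc$mean_cov == 89][1], "single")
  expect_equal(cc$cov_ratio[cc$mean_cov == 89][1], 1)
  # 204/89 = 2.29: between double and triple coverage
  expect_equal(cc$copy_class[cc$mean_cov == 204], "intermediate(2,3)")
  expect_true(cc$repeat_like[cc$mean_cov == 204])
  # 178/89 = 2.00: clean double coverage
  expect_equal(cc$copy_class[cc$mean_cov == 178], "multiple(2)")
  # 50/89 = 0.56: low-coverage (substoichiometric) class
  expect_equal(cc$copy_class[cc$mean_cov == 50], "low")
  expect_false(cc$repeat_like[cc$mean_cov == 110])

  expect_error(assign_copy_class(contigs[1:2, ]), "at least 3")
  zero <- contigs; zero$mean_cov <- 0
  expect_error(assign_copy_class(zero), "median")
})

test_that("noise-free coverage recovers the true copy structure", {
  for (seed in c(2, 6)) {
    cfg <- small_genome_cfg(seed)
    tr <- simulate_mitogenome(cfg)
    fr <- fragment_to_contigs(tr, noise_cv = 0)
    cc <- select_all(fr$contigs)
    truth <- setNames(tr$contig_truth$expected_rel_cov, tr$contig_truth$id)
    for (i in seq_len(nrow(cc))) {
      if (truth[[cc$id[i]]] >= 2) expect_true(cc$repeat_like[i])
      else expect_equal(cc$copy_class[i], "single")
    }
  }
})
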