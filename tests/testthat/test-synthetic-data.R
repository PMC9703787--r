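test_that("simulation is bit-reproducible and honours the no-repeat case", {
  cfg <- sim_config(seed = 3, n_unique_segments = 5,
                    unique_len_range = c(2000, 4000), n_repeat_families = 0,
                    n_molecules = 2)
  t1 <- simulate_mitogenome(cfg)
  t2 <- simulate_mitogenome(cfg)
  expect_identical(t1, t2)
  # no repeats: every adjacency occurs exactly once, relative coverage is
  # the stoichiometry
  key <- with(t1$junctions, paste(from_id, from_ori, to_id, to_ori))
  expect_false(any(duplicated(key)))
  expect_true(all(t1$contig_truth$expected_rel_cov == 1))

  lr1 <- simulate_long_reads(t1, list(mean_len = 2500, depth = 5))
  lr2 <- simulate_long_reads(t2, list(mean_len = 2500, depth = 5))
  expect_identical(lr1, lr2)
})

test_that("expected relative coverage counts genomic copies times stoichiometry", {
  cfg <- sim_config(seed = 5, unique_len_range = c(2000, 3000),
                    molecules = list(
                      list(id = "m1", circular = FALSE, copies = 1,
                           layout = c("U1", "R1", "U2", "R1", "U3")),
                      list(id = "m2", circular = FALSE, copies = 1,
                           layout = c("U4", "R1", "U5", "R1", "U6"))))
  tr <- simulate_mitogenome(cfg)
  got <- tr$contig_truth$expected_rel_cov[tr$contig_truth$id == "R1"]
  expect_equal(got, 4)
  # brute-force position count over the emitted molecules
  unit <- tr$elements[["R1"]]
  hits <- sum(vapply(tr$molecules$sequence, function(m)
    length(gregexpr(unit, m, fixed = TRUE)[[1]]), numeric(1)))
  expect_equal(hits, 4)
})

test_that("fragment_to_contigs collapses repeats and scales coverage by copy number", {
  cfg <- sim_config(seed = 8, unique_len_range = c(3000, 5000),
                    molecules = list(
                      list(id = "m1", circular = FALSE, copies = 1,
                           layout = c("U1", "U2", "U3"))))
  tr <- simulate_mitogenome(cfg)
  fr <- fragment_to_contigs(tr, base_depth = 89, noise_cv = 0)
  expect_equal(nrow(fr$contigs), 3)
  expect_true(all(fr$contigs$mean_cov == 89))

  cfg2 <- sim_config(seed = 9, unique_len_range = c(3000, 5000),
                     molecules = list(
                       list(id = "m1", circular = TRUE, copies = 1,
                            layout = c("U1", "R1", "U2", "R1"))))
  tr2 <- simulate_mitogenome(cfg2)
  fr2 <- fragment_to_contigs(tr2, base_depth = 89, noise_cv = 0)
  expect_setequal(fr2$contigs$id, c("U1", "U2", "R1"))
  expect_equal(fr2$contigs$mean_cov[fr2$contigs$id == "R1"], 178)
  expect_true(all(fr2$contigs$mean_cov[fr2$contigs$id != "R1"] == 89))
})

test_that("error-free long reads are substrings of their molecules and hit the target depth", {
  cfg <- small_genome_cfg(seed = 14)
  tr <- simulate_mitogenome(cfg)
  lr <- simulate_long_reads(tr, list(depth = 20))
  doubled <- setNames(ifelse(tr$molecules$circular,
                             paste0(tr$molecules$sequence,
                                    tr$molecules$sequence),
                             tr$molecules$sequence), tr$molecules$id)
  for (i in seq_len(min(25, nrow(lr)))) {
    s <- lr$sequence[i]
    found <- any(vapply(doubled, function(d)
      grepl(s, d, fixed = TRUE) || grepl(revcomp(s), d, fixed = TRUE),
      logical(1)))
    expect_true(found)
  }
  total <- sum(tr$molecules$length * tr$molecules$copies)
  expect_lt(abs(sum(nchar(lr$sequence)) - 20 * total), 0.1 * 20 * total)
  expect_error(simulate_long_reads(tr, list(mean_len = 10 * max(tr$molecules$length))),
               "molecule length")
})

test_that("short-read simulation respects pairing constraints and errors out on bad specs", {
  cfg <- small_genome_cfg(seed = 15, n_unique = 4, n_rep = 0)
  tr <- simulate_mitogenome(cfg)
  sr <- simulate_short_reads(tr, list(depth = 5))
  expect_equal(nrow(sr$read1), nrow(sr$read2))
  expect_true(all(nchar(sr$read1$sequence) == 150))
  expect_error(simulate_short_reads(tr, list(insert_size = 200)),
               "twice the read length")
})

test_that("genomic material is conserved between molecules and contig expectations", {
  for (seed in 1:5) {
    cfg <- sim_config(seed = seed, n_unique_segments = 6,
                      unique_len_range = c(2000, 6000),
                      n_repeat_families = 2,
                      repeat_len_mixture = list(p_bulk = 0.5,
                                                bulk_range = c(50, 200),
                                                tail_range = c(500, 1500)),
                      n_molecules = 2, stoichiometry = c(1, 2))
    tr <- simulate_mitogenome(cfg)
    lhs <- sum(nchar(tr$elements[tr$contig_truth$id]) *
                 tr$contig_truth$expected_rel_cov)
    rhs <- sum(tr$molecules$length * tr$molecules$copies)
    expect_equal(lhs, rhs)
  }
})

test_that("emitted GC tracks the configured target on large genomes", {
  cfg <- sim_config(seed = 31, n_unique_segments = 5,
                    unique_len_range = c(12000, 20000),
                    n_repeat_families = 0, n_molecules = 1,
                    gc_target = 0.46)
  tr <- simulate_mitogenome(cfg)
  expect_gte(sum(tr$molecules$length), 50000)
  gc <- assembly_stats(tr$molecules[, c("id", "sequence")])$gc_fraction
  expect_lt(abs(gc - 0.46), 0.03)
})

test_that("planted MTPTs are recorded in both coordinate systems and recoverable", {
  cfg <- sim_config(seed = 21, n_unique_segments = 6,
                    unique_len_range = c(9000, 16000),
                    n_repeat_families = 0, n_molecules = 2,
                    mtpt_spec = list(n_inserts = 7,
                                     insert_len_range = c(100, 1500),
                                     identity = 0.95))
  tr <- simulate_mitogenome(cfg)
  pl <- simulate_plastome(30000, seed = 77)
  expect_identical(plant_mtpts(tr, pl, list(n_inserts = 0)), tr)
  expect_error(plant_mtpts(tr, pl, list(identity = 1.5)), "identity")

  tr2 <- plant_mtpts(tr, pl)
  expect_equal(nrow(tr2$mtpt_truth), 7)
  # every recorded insert matches the plastome window at ~95% identity
  for (i in seq_len(nrow(tr2$mtpt_truth))) {
    mt <- tr2$mtpt_truth[i, ]
    ins <- substr(tr2$molecules$sequence[tr2$molecules$id == mt$molecule],
                  mt$start, mt$end)
    src <- substr(pl$sequence, mt$p_start, mt$p_end)
    if (mt$strand == "-") src <- revcomp(src)
    expect_equal(nchar(ins), nchar(src))
    ident <- mean(strsplit(ins, "")[[1]] == strsplit(src, "")[[1]])
    expect_gt(ident, 0.90)
  }
  # recovery through the MTPT detector, one region per planted insert
  mt <- find_mtpts(tr2$molecules[, c("id", "sequence")], pl)
  expect_equal(nrow(mt$regions), 7)
  for (i in seq_len(nrow(tr2$mtpt_truth))) {
    tru <- tr2$mtpt_truth[i, ]
    hit <- mt$regions[mt$regions$seq_id == tru$molecule &
                        abs(mt$regions$start - tru$start) <= 10 &
                        abs(mt$regions$end - tru$end) <= 10, ]
    expect_equal(nrow(hit), 1)
  }
  # identity-1.0 insert recovered at 100%
  tr3 <- plant_mtpts(simulate_mitogenome(sim_config(
    seed = 22, n_unique_segments = 3, unique_len_range = c(5000, 8000),
    n_repeat_families = 0, n_molecules = 1)), pl,
    list(n_inserts = 1, insert_len_range = c(400, 400), identity = 1.0))
  mt3 <- find_mtpts(tr3$molecules[, c("id", "sequence")], pl)
  expect_equal(nrow(mt3$regions), 1)
  expect_equal(mt3$regions$identity, 1.0)
})
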