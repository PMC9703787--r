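test_that("the short-read mapper honours the similarity contract and best-hit semantics", {
  withr::local_seed(81)
  ref <- random_dna(4000)
  refs <- data.frame(id = "ref", sequence = ref)
  exact <- substr(ref, 1001, 1150)
  mut <- function(s, n) {
    ch <- strsplit(s, "")[[1]]
    at <- sample(length(ch), n)
    ch[at] <- chartr("ACGT", "CGTA", ch[at])
    paste(ch, collapse = "")
  }
  reads <- data.frame(
    id = c("exact", "rc", "mm15", "alien"),
    sequence = c(exact, revcomp(substr(ref, 2001, 2150)),
                 mut(substr(ref, 3001, 3150), 15), random_dna(150)))
  pl <- map_short_reads(reads, refs, map_params(similarity = 0.95))
  rm <- attr(pl, "read_map")
  expect_true(rm$mapped[rm$id == "exact"])
  expect_equal(rm$strand[rm$id == "rc"], "-")
  # 10% mismatches fall below similarity 0.95
  expect_false(rm$mapped[rm$id == "mm15"])
  expect_false(rm$mapped[rm$id == "alien"])
  # the exact read contributes depth 1 over exactly its span
  depth <- colSums(pl$ref$counts[1:4, ])
  expect_true(all(depth[1001:1150] >= 1))
  expect_equal(sum(depth), 2 * 150) # two mapped reads at similarity 0.95

  # raising similarity never maps more reads (anti-monotone)
  pl90 <- map_short_reads(reads, refs, map_params(similarity = 0.90))
  rm90 <- attr(pl90, "read_map")
  expect_true(all(rm$mapped <= rm90$mapped))
  expect_true(rm90$mapped[rm90$id == "mm15"])

  # equal best hits at two loci are discarded as ambiguous
  two <- data.frame(id = "two", sequence = paste0(ref, random_dna(500), ref))
  plam <- map_short_reads(data.frame(id = "a", sequence = exact), two,
                          map_params())
  expect_true(attr(plam, "read_map")$ambiguous[1])

  expect_error(map_short_reads(reads, data.frame(id = character(0),
                                                 sequence = character(0))),
               "empty reference")
})

test_that("simulated depth-30 reads give a mean pileup depth near 30", {
  cfg <- sim_config(seed = 82, n_unique_segments = 2,
                    unique_len_range = c(8000, 10000), n_repeat_families = 0,
                    n_molecules = 1, circular_molecules = integer(0))
  tr <- simulate_mitogenome(cfg)
  sr <- simulate_short_reads(tr, list(depth = 30))
  refs <- tr$molecules[, c("id", "sequence")]
  pl <- map_short_reads(sr, refs)
  depth <- colSums(pl[[1]]$counts[1:4, ])
  expect_lt(abs(mean(depth) - 30), 0.15 * 30)
})

test_that("plastid-derived reads are removed while mitochondrial reads survive", {
  withr::local_seed(83)
  plastome <- simulate_plastome(20000, seed = 83)
  mito <- random_dna(20000)
  starts <- seq(1, 19000, by = 200)
  reads <- rbind(
    data.frame(id = sprintf("cp%03d", seq_along(starts)),
               sequence = substr(plastome$sequence, starts, starts + 149)),
    data.frame(id = sprintf("mt%03d", seq_along(starts)),
               sequence = substr(mito, starts, starts + 149)))
  kept <- remove_plastid_reads(reads, plastome)
  expect_true(all(grepl("^mt", kept$id)))
  expect_equal(nrow(kept), length(starts))
})

test_that("consensus extraction follows the low-coverage threshold rules", {
  # hand-built pileup over a 10 bp reference
  ref <- "ACGTACGTAC"
  counts <- matrix(0L, 5, 10, dimnames = list(c("A", "C", "G", "T", "del")))
  # positions 1..8 covered 6x agreeing with reference, except position 3
  # where reads vote G->T
  for (i in 1:8) {
    b <- substr(ref, i, i)
    counts[b, i] <- 6L
  }
  counts["G", 3] <- 0L; counts["T", 3] <- 6L
  # position 9: depth 4 (below threshold 5) voting against the reference
  counts["A", 9] <- 0L; counts["G", 9] <- 4L
  pu <- structure(list(ref_id = "r", ref_len = 10, counts = counts,
                       insertions = data.frame(pos = integer(0),
                                               seq = character(0),
                                               count = integer(0))),
                  class = "pileup")
  cons <- extract_consensus(pu, ref, low_cov_threshold = 5)
  expect_equal(substr(cons$sequence, 3, 3), "T")   # corrected
  expect_equal(substr(cons$sequence, 9, 9), "A")   # reference retained
  expect_equal(cons$low_coverage, data.frame(start = 9, end = 10))
  # ties go to the reference base
  counts2 <- counts; counts2["G", 3] <- 6L
  pu2 <- pu; pu2$counts <- counts2
  expect_equal(substr(extract_consensus(pu2, ref, 5)$sequence, 3, 3), "G")
  # zero coverage everywhere: unchanged, one full-length interval
  pu0 <- pu; pu0$counts <- matrix(0L, 5, 10)
  cons0 <- extract_consensus(pu0, ref, 5)
  expect_equal(cons0$sequence, ref)
  expect_equal(cons0$low_coverage, data.frame(start = 1, end = 10))
  # optional N fill at low coverage
  consn <- extract_consensus(pu, ref, 5, low_cov_action = "n")
  expect_equal(substr(consn$sequence, 9, 10), "NN")
  # majority deletions and insertions are applied
  counts3 <- counts
  counts3["T", 4] <- 0L; counts3["del", 4] <- 6L
  pu3 <- pu; pu3$counts <- counts3
  pu3$insertions <- data.frame(pos = 6, seq = "GG", count = 5)
  cons3 <- extract_consensus(pu3, ref, 5)
  expect_equal(cons3$sequence, "ACTACGGGTAC")
})

test_that("planted substitutions are corrected by unanimous 30x reads", {
  cfg <- sim_config(seed = 84, n_unique_segments = 2,
                    unique_len_range = c(6000, 8000), n_repeat_families = 0,
                    n_molecules = 1, circular_molecules = integer(0))
  tr <- simulate_mitogenome(cfg)
  sr <- simulate_short_reads(tr, list(depth = 30))
  truth_seq <- tr$molecules$sequence[1]
  broken <- truth_seq
  substr(broken, 3000, 3000) <- chartr("ACGT", "CGTA",
                                       substr(broken, 3000, 3000))
  pl <- map_short_reads(sr, data.frame(id = "m", sequence = broken))
  cons <- extract_consensus(pl$m, broken, 5)
  expect_equal(cons$sequence, truth_seq)
})

test_that("junctions filled from 5%-error reads polish back to the exact molecules", {
  cfg <- small_genome_cfg(seed = 85, error_rate = 0.05)
  tr <- simulate_mitogenome(cfg)
  fr <- fragment_to_contigs(tr, noise_cv = 0)
  lr <- simulate_long_reads(tr)
  sr <- simulate_short_reads(tr, list(depth = 30))
  sel <- select_all(fr$contigs)
  ss <- build_scaffolds(sel[sel$selected, ], lr)
  pol <- polish_scaffolds(ss, sr)
  for (i in seq_len(nrow(pol$scaffolds))) {
    expect_true(matches_truth_molecule(pol$scaffolds$sequence[i],
                                       pol$scaffolds$circular[i], tr))
    expect_false(grepl("N", pol$scaffolds$sequence[i], fixed = TRUE))
  }
  # polishing is a fixed point on already-perfect scaffolds
  pol2 <- polish_scaffolds(pol$scaffolds, sr)
  expect_identical(pol2$scaffolds$sequence, pol$scaffolds$sequence)
})
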