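# hand-built two-contig genome: molecule = A + B, reads placed by hand so
# support counts are known exactly
two_contig_fixture <- function(n_span = 5) {
  withr::local_seed(61, .local_envir = parent.frame())
  A <- random_dna(12000); B <- random_dna(12000)
  mol <- paste0(A, B)
  contigs <- data.frame(id = c("A", "B"), sequence = c(A, B),
                        copy_class = "single", repeat_like = FALSE,
                        stringsAsFactors = FALSE)
  # spanning reads: >= 10 kb of A's 3' end plus part of B
  starts <- seq(1000, by = 200, length.out = n_span)
  reads <- data.frame(id = sprintf("sp%02d", seq_len(n_span)),
                      sequence = substr(mol, starts, starts + 15000),
                      stringsAsFactors = FALSE)
  list(contigs = contigs, reads = reads, mol = mol, A = A, B = B)
}

test_that("connection evidence counts qualifying spanning reads per seed end", {
  fx <- two_contig_fixture(n_span = 5)
  # one extra read anchored only in A, far from the junction: no evidence
  extra <- data.frame(id = "inA", sequence = substr(fx$A, 1, 11000))
  ev <- collect_connection_evidence("A", fx$contigs,
                                    rbind(fx$reads, extra))
  e3 <- ev[ev$end == "3'", ]
  expect_equal(e3$partner, "B")
  expect_equal(e3$p_ori, "+")
  expect_equal(e3$support, 5)
  expect_equal(nrow(ev[ev$end == "5'", ]), 0)
})

test_that("connections need at least min_support reads", {
  fx <- two_contig_fixture(n_span = 2)
  ss <- build_scaffolds(fx$contigs, fx$reads)
  expect_equal(length(ss$scaffolds), 2) # stays split at support 2
  ss3 <- build_scaffolds(fx$contigs, fx$reads,
                         scaffold_params(min_support = 2))
  expect_equal(length(ss3$scaffolds), 1)
})

test_that("raising min_support never adds a connection", {
  cfg <- small_genome_cfg(seed = 62, lr_depth = 8)
  tr <- simulate_mitogenome(cfg)
  fr <- fragment_to_contigs(tr, noise_cv = 0)
  lr <- simulate_long_reads(tr)
  sel <- select_all(fr$contigs)
  n_junctions <- function(ms) {
    ss <- build_scaffolds(sel[sel$selected, ], lr,
                          scaffold_params(min_support = ms))
    sum(vapply(ss$scaffolds, function(s) nrow(s$placements) - 1, numeric(1)))
  }
  n3 <- n_junctions(3); n5 <- n_junctions(5); n8 <- n_junctions(8)
  expect_gte(n3, n5)
  expect_gte(n5, n8)
})

test_that("a linear molecule of unique contigs is reconstructed exactly", {
  cfg <- sim_config(seed = 63, n_unique_segments = 5,
                    unique_len_range = c(9000, 14000),
                    n_repeat_families = 0, n_molecules = 1,
                    circular_molecules = integer(0),
                    long_read_spec = list(mean_len = 14000, sdlog = 0.35,
                                          min_len = 1000, error_rate = 0,
                                          depth = 15))
  tr <- simulate_mitogenome(cfg)
  fr <- fragment_to_contigs(tr, noise_cv = 0)
  lr <- simulate_long_reads(tr)
  sel <- select_all(fr$contigs)
  ss <- build_scaffolds(sel[sel$selected, ], lr)
  expect_equal(length(ss$scaffolds), 1)
  expect_false(ss$scaffolds[[1]]$circular)
  acc <- scaffold_accuracy(ss, tr)
  expect_equal(acc$recall, 1)
  expect_equal(acc$false_adjacencies, 0)
  expect_true(matches_truth_molecule(ss$scaffolds[[1]]$sequence, FALSE, tr))
})

test_that("a repeat between two flanking pairs is multi-placed and reported with 4 partners", {
  cfg <- sim_config(seed = 64, unique_len_range = c(10000, 14000),
                    repeat_len_mixture = list(p_bulk = 0,
                                              bulk_range = c(50, 200),
                                              tail_range = c(5000, 6000)),
                    molecules = list(
                      list(id = "m1", circular = FALSE, copies = 1,
                           layout = c("UA", "R1", "UB")),
                      list(id = "m2", circular = FALSE, copies = 1,
                           layout = c("UC", "R1", "UD"))),
                    long_read_spec = list(mean_len = 14000, sdlog = 0.35,
                                          min_len = 1000, error_rate = 0,
                                          depth = 15))
  tr <- simulate_mitogenome(cfg)
  fr <- fragment_to_contigs(tr, noise_cv = 0)
  lr <- simulate_long_reads(tr)
  sel <- select_all(fr$contigs)
  ss <- build_scaffolds(sel[sel$selected, ], lr)
  in_scaffolds <- vapply(ss$scaffolds, function(s)
    "R1" %in% s$placements$contig, logical(1))
  expect_equal(sum(in_scaffolds), 2)
  rep_partners <- ss$adjacency_report[ss$adjacency_report$contig == "R1", ]
  expect_setequal(rep_partners$partner, c("UA", "UB", "UC", "UD"))
  expect_equal(nrow(rep_partners), 4)
  acc <- scaffold_accuracy(ss, tr)
  expect_equal(acc$recall, 1)
  expect_equal(acc$false_adjacencies, 0)
})

test_that("circular molecules are flagged circular and linear ones are not", {
  cfg <- small_genome_cfg(seed = 65)
  tr <- simulate_mitogenome(cfg)
  fr <- fragment_to_contigs(tr, noise_cv = 0)
  lr <- simulate_long_reads(tr)
  sel <- select_all(fr$contigs)
  ss <- build_scaffolds(sel[sel$selected, ], lr)
  ncirc_truth <- sum(tr$molecules$circular)
  expect_equal(sum(vapply(ss$scaffolds, `[[`, logical(1), "circular")),
               ncirc_truth)
  # standalone detector agrees per scaffold
  for (sc in ss$scaffolds) {
    expect_equal(detect_circularity(data.frame(contig = sc$placements$contig,
                                               ori = sc$placements$orientation),
                                    sel[sel$selected, ], lr),
                 sc$circular)
  }
})

test_that("contig overlap implied by read alignment is emitted once", {
  withr::local_seed(66)
  X <- random_dna(24000)
  contigs <- data.frame(id = c("A", "B"),
                        sequence = c(substr(X, 1, 12050),
                                     substr(X, 11951, 24000)),
                        copy_class = "single", repeat_like = FALSE,
                        stringsAsFactors = FALSE)
  starts <- seq(500, by = 150, length.out = 5)
  reads <- data.frame(id = sprintf("r%d", 1:5),
                      sequence = substr(X, starts, starts + 15000))
  ss <- build_scaffolds(contigs, reads)
  expect_equal(length(ss$scaffolds), 1)
  s <- ss$scaffolds[[1]]$sequence
  expect_true(s == X || revcomp(s) == X)
})

test_that("scaffold membership is invariant to contig input order", {
  cfg <- small_genome_cfg(seed = 67)
  tr <- simulate_mitogenome(cfg)
  fr <- fragment_to_contigs(tr, noise_cv = 0)
  lr <- simulate_long_reads(tr)
  sel <- select_all(fr$contigs)
  sets_of <- function(ss) {
    s <- lapply(ss$scaffolds, function(x) sort(paste(x$placements$contig,
                                                     x$placements$orientation)))
    sort(vapply(s, paste, character(1), collapse = ";"))
  }
  ss1 <- build_scaffolds(sel[sel$selected, ], lr)
  perm <- sel[sel$selected, ]
  perm <- perm[rev(seq_len(nrow(perm))), ]
  ss2 <- build_scaffolds(perm, lr)
  s1 <- sets_of(ss1); s2 <- sets_of(ss2)
  # identical up to global reverse complement of whole scaffolds
  rc_set <- function(x) {
    parts <- strsplit(x, ";")[[1]]
    toks <- do.call(rbind, strsplit(parts, " "))
    paste(sort(paste(toks[, 1], ifelse(toks[, 2] == "+", "-", "+"))),
          collapse = ";")
  }
  match2 <- vapply(seq_along(s1), function(i)
    s1[i] %in% s2 || rc_set(s1[i]) %in% s2, logical(1))
  expect_true(all(match2))
})

test_that("error-free truth recovery holds across random multipartite genomes", {
  for (seed in c(71, 72, 73, 74)) {
    cfg <- small_genome_cfg(seed)
    tr <- simulate_mitogenome(cfg)
    fr <- fragment_to_contigs(tr, noise_cv = 0)
    lr <- simulate_long_reads(tr)
    sel <- select_all(fr$contigs)
    ss <- build_scaffolds(sel[sel$selected, ], lr)
    acc <- scaffold_accuracy(ss, tr)
    expect_equal(acc$recall, 1)
    expect_equal(acc$false_adjacencies, 0)
    for (sc in ss$scaffolds)
      expect_true(matches_truth_molecule(sc$sequence, sc$circular, tr))
  }
})
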