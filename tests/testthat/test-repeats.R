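test_that("maximal repeat enumeration matches the brute-force pair-extension oracle", {
  set.seed(91)
  for (t in 1:15) {
    n <- sample(300:1200, 1)
    s <- random_dna(n, 0.45)
    if (t %% 3 == 0) { # plant a direct + inverted pair
      u <- random_dna(sample(25:60, 1), 0.45)
      s <- plant_repeat(s, u, sort(sample(50:(n - 80), 2)), rc = TRUE)
    }
    if (t %% 3 == 1) { # plant a three-copy direct repeat
      u <- random_dna(sample(25:50, 1), 0.45)
      s <- plant_repeat(s, u, sort(sample(50:(n - 80), 3)))
    }
    rs <- find_repeats(c(x = s), min_len = 20)
    impl <- sort(unname(rs$units))
    orc <- oracle_repeat_units(c(x = s), 20)
    expect_identical(impl, orc)
  }
})

test_that("random sequence carries no long repeats; planted units are recovered exactly", {
  withr::local_seed(92)
  s <- random_dna(10000)
  expect_equal(nrow(find_repeats(c(x = s), min_len = 24)$families), 0)

  u <- random_dna(100)
  s2 <- plant_repeat(random_dna(1000), u, c(200, 600))
  rs <- find_repeats(c(x = s2), min_len = 50)
  expect_equal(nrow(rs$families), 1)
  expect_equal(rs$families$unit_length, 100)
  expect_equal(rs$families$copy_number, 2)
  expect_equal(unname(rs$units[1]),
               if (u <= revcomp(u)) u else revcomp(u))
  cp <- rs$copies
  # planted sites shift by guard bases and the earlier insertion
  expect_equal(sort(cp$start), c(202, 704))
})

test_that("head-to-tail copies count as tandem and leave the interspersed set", {
  withr::local_seed(93)
  u <- random_dna(100)
  left <- random_dna(400); right <- random_dna(400)
  tandem <- paste0(left, u, u, right)
  rs <- find_repeats(c(x = tandem), min_len = 50)
  expect_equal(nrow(rs$families), 0)
  # the same two copies spread apart are interspersed
  spread <- paste0(left, u, right, u)
  rs2 <- find_repeats(c(x = spread), min_len = 50)
  expect_equal(nrow(rs2$families), 1)
})

test_that("repeat proportion accounting modes agree with forced arithmetic", {
  withr::local_seed(94)
  u <- random_dna(100)
  # 1,000 bp total with two disjoint copies (guard bases keep the unit
  # at exactly 100 bp)
  s <- plant_repeat(random_dna(796), u, c(200, 500))
  expect_equal(nchar(s), 1000)
  rs <- find_repeats(c(x = s), min_len = 50)
  expect_equal(repeat_proportion(rs, mode = "union"), 0.200)
  expect_equal(repeat_proportion(rs, mode = "family_sum"), 0.100)
  expect_equal(repeat_proportion(rs, mode = "all_copies"), 0.200)
  expect_error(repeat_proportion(rs, mode = "bogus"))
  empty <- find_repeats(c(x = random_dna(5000)), min_len = 24)
  for (m in c("union", "family_sum", "all_copies"))
    expect_equal(repeat_proportion(empty, mode = m), 0)
})

test_that("repeat summary restricts by unit length and bins sizes", {
  rs <- structure(list(
    families = data.frame(family_id = c("RF0001", "RF0002", "RF0003",
                                        "RF0004"),
                          unit_length = c(60, 500, 12000, 30),
                          copy_number = c(2, 3, 2, 5)),
    copies = NULL, units = NULL, min_len = 24, total_len = 1e5),
    class = "repeat_set")
  sm <- repeat_summary(rs, min_len = 50)
  expect_equal(sm$count, 3)
  expect_equal(sm$mean_unit_length, 4186.7, tolerance = 1e-4)
  expect_equal(sm$mean_copy_number, 2.33, tolerance = 1e-2)
  expect_equal(sm$size_histogram$count, c(1, 1, 0, 1))
  single <- repeat_summary(structure(list(
    families = data.frame(family_id = "RF0001", unit_length = 100,
                          copy_number = 2)), class = "repeat_set"))
  expect_equal(single$count, 1)
  expect_equal(single$mean_unit_length, 100)
  expect_equal(single$mean_copy_number, 2)
})

test_that("lowering min_len never loses families or proportion", {
  withr::local_seed(95)
  s <- random_dna(3000)
  for (u_len in c(30, 60, 120)) {
    u <- random_dna(u_len)
    s <- plant_repeat(s, u, sort(sample(100:2500, 2)))
  }
  r24 <- find_repeats(c(x = s), min_len = 24)
  r50 <- find_repeats(c(x = s), min_len = 50)
  r100 <- find_repeats(c(x = s), min_len = 100)
  expect_gte(nrow(r24$families), nrow(r50$families))
  expect_gte(nrow(r50$families), nrow(r100$families))
  expect_gte(repeat_proportion(r24), repeat_proportion(r50))
  expect_gte(repeat_proportion(r50), repeat_proportion(r100))
})

test_that("union proportion is rotation-invariant for a circular genome", {
  withr::local_seed(96)
  u <- random_dna(200)
  g <- plant_repeat(random_dna(20000), u, c(4000, 12000))
  rot <- function(s, k) paste0(substr(s, k + 1, nchar(s)), substr(s, 1, k))
  p0 <- repeat_proportion(find_repeats(c(x = g), min_len = 50))
  p1 <- repeat_proportion(find_repeats(c(x = rot(g, 7000)), min_len = 50))
  expect_equal(p0, p1, tolerance = 0.005)
})

test_that("MTPT detection handles identity, absence and self-comparison", {
  withr::local_seed(97)
  pl <- simulate_plastome(20000, seed = 97)
  # unrelated sequence: nothing found
  none <- find_mtpts(c(m = random_dna(20000)), pl)
  expect_equal(nrow(none$regions), 0)
  expect_equal(none$proportion, 0)
  # self-comparison: one region covering everything at identity 1
  self <- find_mtpts(pl, pl)
  expect_equal(nrow(self$regions), 1)
  expect_equal(self$regions$start, 1)
  expect_equal(self$regions$end, 20000)
  expect_equal(self$regions$identity, 1)
  expect_equal(self$proportion, 1)
})
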