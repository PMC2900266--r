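table4_mrna <- c(simultaneous = 2623, delayed_1 = 4410, delayed_2 = 4501,
                 delayed_3 = 7762, none = 5724)
table4_prot <- c(simultaneous = 5016, delayed_1 = 7344, delayed_2 = 5606,
                 delayed_3 = 4092, none = 2962)

test_that("pair sampling is uniform-without-replacement and seeded", {
  ids <- sprintf("g%04d", 1:2502)
  pw <- sample_pairs(ids, n = 25020, seed = 1)
  expect_identical(nrow(pw), 25020L)
  expect_identical(anyDuplicated(paste(pw$id_x, pw$id_y)), 0L)
  expect_true(all(pw$id_x != pw$id_y))                    # no self-pairs
  # unordered pairs are canonical, so no reversed duplicates either
  expect_identical(anyDuplicated(paste(pmin(pw$id_x, pw$id_y),
                                       pmax(pw$id_x, pw$id_y))), 0L)
  expect_identical(sample_pairs(ids, n = 100, seed = 9),
                   sample_pairs(ids, n = 100, seed = 9))

  small <- letters[1:5]
  expect_error(sample_pairs(small, n = 11), "available")
  expect_identical(nrow(sample_pairs(small, n = 0)), 0L)

  pc <- sample_pairs(small, small, n = 20, cross_level = TRUE, seed = 2)
  expect_identical(nrow(pc), 20L)
  expect_true(all(pc$id_x != pc$id_y))                    # same-gene excluded
  expect_error(sample_pairs(small, small, n = 21, cross_level = TRUE),
               "available")
})

test_that("class tabulation reproduces published-style percentages", {
  ct <- tabulate_classes(table4_mrna)
  expect_equal(unname(ct$percentages),
               c(10.48, 17.63, 17.99, 31.02, 22.88))
  expect_equal(ct$time_delayed_pct, 66.64)
  expect_identical(ct$n, 25020)
  # percentages track count/denominator to within rounding
  expect_true(all(abs(ct$percentages - 100 * ct$counts / ct$n) <= 0.005))
  expect_lte(abs(sum(ct$percentages) - 100), 0.05 * length(ct$counts))

  pooled <- tabulate_classes(table4_prot, pooled = TRUE)
  expect_equal(unname(pooled$counts),
               c(5016, 7344 + 5606 + 4092, 2962))

  single <- tabulate_classes(c(simultaneous = 12))
  expect_equal(unname(single$percentages), 100)
})

test_that("tabulation of results excludes untestable pairs", {
  res <- data.frame(class = c("simultaneous", "delayed_2", "none",
                              "untestable", "delayed_2"),
                    gamma = c(1, 0.9, 0.1, NA, -0.95))
  ct <- tabulate_classes(res, max_delay = 3)
  expect_identical(ct$n, 4)
  expect_identical(ct$n_untestable, 1L)
  expect_equal(unname(ct$counts), c(1, 0, 2, 0, 1))
  expect_error(tabulate_classes(res[0, ]), "empty")
})

test_that("transfer analysis reproduces the published worked example", {
  counts <- matrix(c(593, 1751, 279,
                     3383, 11364, 1926,
                     1065, 4003, 656),
                   nrow = 3, byrow = TRUE,
                   dimnames = list(c("simultaneous", "time_delayed", "none"),
                                   c("simultaneous", "time_delayed", "none")))
  tm <- transfer_matrix(counts)
  expect_identical(tm$total, 25020)
  expect_equal(tm$conserved_fraction, 50.41)
  expect_equal(tm$coexpressed_both, 68.31)
  expect_equal(unname(tm$origin_pct["simultaneous", ]),
               c(22.61, 66.76, 10.64))
  expect_lte(abs(sum(tm$origin_pct["simultaneous", ]) - 100), 0.05 * 3)
})

test_that("transfer of identical classifications is fully conserved", {
  res <- data.frame(id_x = letters[1:6], id_y = LETTERS[1:6],
                    class = c("simultaneous", "delayed_1", "delayed_3",
                              "none", "none", "untestable"),
                    stringsAsFactors = FALSE)
  tm <- transfer_analysis(res, res)
  expect_equal(tm$conserved_fraction, 100)
  expect_identical(tm$total, 5)                 # untestable excluded
  # margins equal the pooled class totals of the inputs
  ct <- tabulate_classes(res, pooled = TRUE)
  expect_equal(unname(rowSums(tm$counts)), unname(as.numeric(ct$counts)))

  other <- res; other$id_y <- rev(other$id_y)
  expect_error(transfer_analysis(res, other), "same pairs")
})

test_that("chi-square contrast matches chisq and a brute-force oracle", {
  cs <- chi_square_2xk(rbind(table4_mrna, table4_prot))
  expect_equal(cs$statistic, 3617.32, tolerance = 0.01 / 3617.32)
  expect_identical(cs$df, 4L)
  expect_lt(cs$p, 0.05)
  expect_equal(cs$statistic, oracle_chisq(rbind(table4_mrna, table4_prot)),
               tolerance = 1e-9)

  expect_equal(chi_square_2xk(rbind(c(10, 20), c(20, 10)))$statistic,
               100 / 15)
  expect_equal(suppressWarnings(
    chi_square_2xk(rbind(c(7, 9, 4), c(7, 9, 4)))$statistic), 0)
  set.seed(60)
  for (i in 1:25) {
    tab <- matrix(rpois(8, 40) + 1, 2, 4)
    expect_equal(chi_square_2xk(tab)$statistic, oracle_chisq(tab),
                 tolerance = 1e-9)
  }
  expect_error(chi_square_2xk(rbind(c(0, 0), c(1, 2))), "margin")
})

test_that("score histograms conserve counts and place mass correctly", {
  res <- data.frame(class = rep("simultaneous", 5), gamma = rep(1, 5))
  h <- gamma_distribution(res, "simultaneous", bins = 20)
  expect_identical(sum(h$count), 5L)
  expect_identical(h$count[20], 5L)            # right-edge bin

  set.seed(14)
  res2 <- data.frame(class = sample(c("delayed_1", "delayed_2"), 200, TRUE),
                     gamma = runif(200, -1, 1))
  h2 <- gamma_distribution(res2, "time_delayed")
  expect_identical(sum(h2$count), 200L)
  expect_error(gamma_distribution(res2, "simultaneous"), "no pairs")
})

test_that("positively biased couplings give positively skewed scores", {
  # generator construction: positive_fraction 0.8 should put most
  # coupled-pair scores on the positive side
  sim <- simulate_coexpression(sim_config(n_genes = 120, seed = 15))
  tr <- sim$truth
  coupled <- tr$pair_id[tr$relationship != "null"]
  g <- vapply(coupled, function(id)
    scan_delays(sim$mrna[id, ], sim$protein[id, ], 3)$best_gamma,
    numeric(1))
  expect_gt(sum(g > 0), sum(g < 0))
})
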