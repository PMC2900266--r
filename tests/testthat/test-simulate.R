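test_that("identical seed and config give bit-identical datasets", {
  cfg <- sim_config(n_genes = 25, n_conditions = 6, seed = 12)
  a <- simulate_coexpression(cfg)
  b <- simulate_coexpression(cfg)
  expect_identical(unclass(a$mrna)[, ], unclass(b$mrna)[, ])
  expect_identical(unclass(a$protein)[, ], unclass(b$protein)[, ])
  expect_identical(a$truth, b$truth)
  c <- simulate_coexpression(sim_config(n_genes = 25, seed = 13))
  expect_false(identical(unclass(a$mrna)[, ], unclass(c$mrna)[, ]))
})

test_that("infeasible or inconsistent configs are rejected", {
  expect_error(sim_config(n_conditions = 5, max_delay = 3), "max_delay")
  expect_error(sim_config(ordered = FALSE, max_delay = 2), "unordered")
  expect_error(sim_config(class_proportions = c(0.5, 0.5)), "entries")
  expect_error(sim_config(max_delay = 1,
                          class_proportions = c(0.5, 0.4, 0.4)), "sum to 1")
  expect_error(sim_config(positive_fraction = 1.2), "positive_fraction")
})

test_that("truth table satisfies its invariants", {
  sim <- simulate_coexpression(sim_config(n_genes = 80, seed = 4))
  tr <- sim$truth
  null <- tr$relationship == "null"
  expect_true(all(tr$lag[null] == 0L))
  expect_true(all(tr$direction[null] == "none"))
  dly <- tr$relationship == "delayed"
  expect_true(all(tr$lag[dly] >= 1L & tr$lag[dly] <= 3L))
  expect_true(all(tr$direction[dly] %in% c("x_leads", "y_leads")))
  expect_true(all(tr$lag[tr$relationship == "simultaneous"] == 0L))
  expect_identical(dim(sim$mrna), c(80L, 6L))
})

test_that("matrices take the six-stage life-cycle shape by default", {
  cfg <- sim_config()
  expect_identical(cfg$n_genes, 2502L)
  expect_identical(cfg$n_conditions, 6L)
  expect_true(cfg$ordered)
  expect_equal(sum(cfg$class_proportions), 1)
})

test_that("noiseless couplings give gamma = 1 at the planted shift", {
  cfg <- sim_config(n_genes = 60, n_conditions = 6, noise_sd = 0,
                    tie_fraction = 0, seed = 99)
  sim <- simulate_coexpression(cfg)
  tr <- sim$truth
  coupled <- which(tr$relationship != "null")
  expect_gt(length(coupled), 20)
  for (k in coupled) {
    id <- tr$pair_id[k]
    sc <- scan_delays(sim$mrna[id, ], sim$protein[id, ], max_delay = 3)
    expect_identical(sc$best_t, tr$lag[k])
    expect_identical(sc$best_direction,
                     scan_direction_for(tr$direction[k], tr$lag[k]))
    s <- if (tr$sign[k] == "positive") 1 else -1
    expect_equal(sc$best_gamma, s * 1)
  }
})

test_that("unordered panels plant only simultaneous and null pairs", {
  cfg <- sim_config(n_genes = 30, n_conditions = 59, ordered = FALSE,
                    max_delay = 0,
                    class_proportions = c(simultaneous = 0.5, null = 0.5),
                    seed = 6)
  sim <- simulate_coexpression(cfg)
  expect_identical(dim(sim$mrna), c(30L, 59L))
  expect_true(all(sim$truth$lag == 0L))
  expect_true(all(sim$truth$relationship %in% c("simultaneous", "null")))
})

test_that("tie_fraction induces tied values", {
  sim <- simulate_coexpression(sim_config(n_genes = 60, tie_fraction = 1,
                                          seed = 2))
  has_tie <- apply(unclass(sim$mrna), 1, function(r) anyDuplicated(r) > 0)
  expect_gt(mean(has_tie), 0.3)
})

test_that("simulation files round-trip through the IO layer", {
  sim <- simulate_coexpression(sim_config(n_genes = 8, seed = 3))
  d <- withr::local_tempdir()
  files <- write_simulation(sim, d)
  m <- read_expression(files[["mrna"]], "mRNA")
  expect_identical(unclass(m)[, ], unclass(sim$mrna)[, ])
  tr <- read.delim(files[["truth"]])
  expect_identical(nrow(tr), 8L)
})

test_that("the golden dataset has its advertised landmarks", {
  g <- golden_small_dataset()
  expect_identical(dim(g$mrna), c(10L, 6L))
  expect_true(anyDuplicated(unclass(g$mrna)["g03", ]) > 0)  # tied values
  expect_equal(spearman_gamma(g$mrna["g02", ], g$protein["g02", ]), -1)
  expect_equal(scan_delays(g$mrna["g04", ], g$protein["g04", ])$best_t, 1L)
  expect_equal(scan_delays(g$mrna["g05", ], g$protein["g05", ])$best_t, 2L)
  # independent pair: permutation p pinned from one run under seed 0
  tp <- test_pair(g$mrna["g06", ], g$protein["g06", ], n_perm = 500,
                  seed = 0)
  expect_gt(tp$p_adjusted, 0.05)
  expect_equal(tp$p_raw, 311 / 501)        # frozen regression value
})
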