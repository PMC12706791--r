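test_that("deviations reproduce the narrated C-7 arithmetic", {
  exp_t <- make_entry("allan", c("C-7", "C-9"), c(144.1, 183.1),
                      c("core_Cq", "carbonyl"))
  calc_t <- make_entry("allan-model", c("C-7", "C-9"), c(135.9, 183.0),
                       c("core_Cq", "carbonyl"), kind = "calculated")
  d <- shift_deviations(exp_t, calc_t)
  expect_equal(d$delta[d$label == "C-7"], -8.2, tolerance = 1e-12)
  expect_equal(abs(d$delta[d$label == "C-7"]), 8.2, tolerance = 1e-12)
  # the well-behaved analogue: 138.1 observed vs 135.9 calculated
  exp_t2 <- make_entry("garci", "C-7", 138.1, "core_Cq")
  calc_t2 <- make_entry("garci-model", "C-7", 135.9, "core_Cq",
                        kind = "calculated")
  expect_equal(abs(shift_deviations(exp_t2, calc_t2)$delta), 2.2,
               tolerance = 1e-12)
})

test_that("deviations apply corrections first and track excluded labels", {
  exp_t <- make_entry("e", c("C-1", "C-4a"), c(157.1, 156.0),
                      c("core_Cq", "core_Cq"))
  calc_t <- make_entry("c", c("C-1", "C-6"), c(160.0, 155.0),
                       c("core_Cq", "core_Cq"), kind = "calculated")
  d <- shift_deviations(exp_t, calc_t, default_corrections())
  expect_equal(d$delta[d$label == "C-1"], 0, tolerance = 1e-12)
  expect_setequal(attr(d, "excluded"), c("C-4a", "C-6"))
  expect_equal(attr(d, "n_shared"), 1)
  # identical entries deviate nowhere
  same <- shift_deviations(exp_t, exp_t)
  expect_true(all(same$delta == 0))
  # disjoint label sets cannot be aligned
  other <- make_entry("c2", "C-8", 120, "core_CH", kind = "calculated")
  expect_error(shift_deviations(exp_t, other),
               class = "pyranoshift_alignment_error")
})

test_that("rmsd and max dev have their closed forms and invariances", {
  dev <- tibble::tibble(label = c("C-1", "C-2"), delta = c(3, -4))
  expect_equal(shift_rmsd(dev), sqrt(12.5), tolerance = 1e-12)
  md <- shift_max_dev(dev)
  expect_equal(md$max_dev, 4)
  expect_equal(md$label, "C-2")
  zero <- tibble::tibble(label = letters[1:3], delta = rep(0, 3))
  expect_equal(shift_rmsd(zero), 0)
  expect_equal(shift_max_dev(zero)$max_dev, 0)
  # permutation invariance and rmsd <= max_dev on random vectors
  set.seed(5)
  for (i in 1:25) {
    d <- tibble::tibble(label = paste0("C-", 1:8),
                        delta = stats::rnorm(8, 0, 3))
    p <- d[sample(8), ]
    expect_equal(shift_rmsd(p), shift_rmsd(d))
    expect_lte(shift_rmsd(d), shift_max_dev(d)$max_dev + 1e-12)
  }
})

test_that("DP4 normalises, respects symmetry, and matches the product oracle", {
  d1 <- tibble::tibble(label = paste0("C-", 1:3), delta = c(1, 1, 1))
  d2 <- tibble::tibble(label = paste0("C-", 1:3), delta = c(3, 3, 3))
  expect_equal(dp4_probabilities(list(only = d1))$dp4, 1.0)
  sym <- dp4_probabilities(list(a = d1, b = dplyr::mutate(d1, delta = -delta)))
  expect_equal(sym$dp4, c(0.5, 0.5), tolerance = 1e-12)
  two <- dp4_probabilities(list(a = d1, b = d2))
  expect_gt(two$dp4[1], 0.9)
  expect_equal(two$dp4, unname(oracle_dp4(list(d1, d2))), tolerance = 1e-10)
  expect_lt(abs(sum(two$dp4) - 1), 1e-9)
  # candidate order does not change the probabilities
  rev2 <- dp4_probabilities(list(b = d2, a = d1))
  expect_equal(rev2$dp4[rev2$candidate_id == "a"], two$dp4[1],
               tolerance = 1e-12)
  # a carbon with identical |delta| in all candidates is uninformative
  aug <- dp4_probabilities(list(
    a = dplyr::bind_rows(d1, tibble::tibble(label = "C-9", delta = 2)),
    b = dplyr::bind_rows(d2, tibble::tibble(label = "C-9", delta = -2))
  ))
  expect_equal(aug$dp4, two$dp4, tolerance = 1e-12)
})

test_that("log-space DP4 equals the direct product whenever it does not underflow", {
  set.seed(9)
  for (i in 1:30) {
    k <- sample(2:4, 1)
    n <- sample(3:12, 1)
    devs <- lapply(seq_len(k), function(j)
      tibble::tibble(label = paste0("C-", seq_len(n)),
                     delta = stats::rnorm(n, 0, 3)))
    names(devs) <- paste0("cand", seq_len(k))
    got <- dp4_probabilities(devs)$dp4
    want <- unname(oracle_dp4(devs))
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("single-outlier flagging follows the narrated pattern", {
  # one 8.2 ppm deviation amid sub-2-ppm residuals
  dev <- tibble::tibble(label = c("C-7", "C-1", "C-2", "C-3"),
                        delta = c(-8.2, 1.1, -0.7, 1.9))
  fl <- flag_single_outlier(dev)
  expect_equal(fl$label, "C-7")
  expect_equal(fl$rmsd_excluding, shift_rmsd(dev[dev$label != "C-7", ]))
  # all deviations small: nothing to flag
  expect_null(flag_single_outlier(
    tibble::tibble(label = paste0("C-", 1:4), delta = c(1, -2, 1.5, 0.3))))
  # two large deviations: not a single-outlier pattern
  expect_null(flag_single_outlier(
    tibble::tibble(label = paste0("C-", 1:4), delta = c(8, 7, 1, 0.5))))
})

test_that("candidate ranking is deterministic and matches direct computation", {
  exp_t <- make_entry("obs", paste0("C-", 1:5),
                      c(160.2, 98.6, 162.4, 93.6, 101.4),
                      c("core_Cq", "core_CH", "core_Cq", "core_CH", "core_CH"))
  cands <- dplyr::bind_rows(
    make_entry("candA", paste0("C-", 1:5),
               c(160.2, 98.6, 162.4, 93.6, 101.4) + c(0.5, -0.5, 0.2, 0, 0.3),
               "core_Cq", kind = "calculated"),
    make_entry("candB", paste0("C-", 1:5),
               c(160.2, 98.6, 162.4, 93.6, 101.4) + c(3, -4, 2, 5, -2),
               "core_Cq", kind = "calculated"),
    make_entry("candC", paste0("C-", 1:5),
               c(160.2, 98.6, 162.4, 93.6, 101.4) + c(1.5, 1.5, -1.5, 1, 1),
               "core_Cq", kind = "calculated")
  )
  rk <- rank_candidates(exp_t, cands)
  # brute-force expectation: order by DP4 computed from the raw deltas
  devs <- list(
    candA = tibble::tibble(delta = c(0.5, -0.5, 0.2, 0, 0.3)),
    candB = tibble::tibble(delta = c(3, -4, 2, 5, -2)),
    candC = tibble::tibble(delta = c(1.5, 1.5, -1.5, 1, 1))
  )
  want <- names(sort(oracle_dp4(devs), decreasing = TRUE))
  expect_equal(rk$candidate_id, want)
  expect_equal(rk$rank, 1:3)
  expect_equal(rk$dp4, unname(sort(oracle_dp4(devs), decreasing = TRUE)),
               tolerance = 1e-10)

  # the experimental entry itself ranks first with zero rmsd
  self <- exp_t
  self$compound_id <- "the-answer"
  self$kind <- "calculated"
  rk2 <- rank_candidates(exp_t, dplyr::bind_rows(self, cands))
  expect_equal(rk2$candidate_id[1], "the-answer")
  expect_equal(rk2$rmsd[1], 0)

  one <- rank_candidates(exp_t, self)
  expect_equal(one$dp4, 1.0)
})

test_that("tied candidates order by rmsd then id", {
  exp_t <- make_entry("obs", paste0("C-", 1:3), c(100, 110, 120), "core_CH")
  # same |delta| multiset => identical DP4; rmsd also ties => id decides
  c1 <- make_entry("zeta", paste0("C-", 1:3), c(101, 109, 121), "core_CH",
                   kind = "calculated")
  c2 <- make_entry("alpha", paste0("C-", 1:3), c(99, 111, 119), "core_CH",
                   kind = "calculated")
  rk <- rank_candidates(exp_t, dplyr::bind_rows(c1, c2))
  expect_equal(rk$candidate_id, c("alpha", "zeta"))
})

test_that("the empirical corrections reduce mean rmsd on offset-bearing sets", {
  worse <- 0
  for (s in 1:20) {
    cfg <- generator_config(n_compounds = 20, noise_sd = 1.0, seed = s)
    ms <- generate_modeling_set(cfg)
    calc <- ms$calculated
    calc$compound_id <- sub("-calc$", "", calc$compound_id)
    joined <- dplyr::inner_join(
      dplyr::select(ms$experimental, "compound_id", "label", "carbon_class",
                    exp_ppm = "shift_ppm"),
      dplyr::select(calc, "compound_id", "label", calc_ppm = "shift_ppm"),
      by = c("compound_id", "label")
    )
    corrected <- dplyr::select(
      apply_corrections(calc, default_corrections()),
      "compound_id", "label", corr_ppm = "shift_ppm")
    joined <- dplyr::inner_join(joined, corrected,
                                by = c("compound_id", "label"))
    per <- joined |>
      dplyr::group_by(.data$compound_id) |>
      dplyr::summarise(
        raw = sqrt(mean((.data$calc_ppm - .data$exp_ppm)^2)),
        corr = sqrt(mean((.data$corr_ppm - .data$exp_ppm)^2)),
        .groups = "drop")
    if (mean(per$corr) >= mean(per$raw)) worse <- worse + 1
  }
  expect_equal(worse, 0)
})
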