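conformer_table <- function(shifts_by_conformer) {
  dplyr::bind_rows(purrr::imap(shifts_by_conformer, function(sh, cf) {
    tibble::tibble(conformer = cf, label = names(sh), shift_ppm = unname(sh))
  }))
}

test_that("Boltzmann averaging reproduces closed-form weights", {
  one <- conformer_table(list(a = c("C-1" = 100)))
  expect_equal(boltzmann_average(one, c(a = 0))$shift_ppm, 100)

  two <- conformer_table(list(a = c("C-1" = 100), b = c("C-1" = 102)))
  expect_equal(boltzmann_average(two, c(a = 3, b = 3))$shift_ppm, 101)

  # energy gap of RT ln 2 gives weights 2/3 and 1/3
  gap <- 8.314e-3 * 298.15 * log(2)
  tri <- conformer_table(list(a = c("C-1" = 100), b = c("C-1" = 103)))
  expect_equal(boltzmann_average(tri, c(a = 0, b = gap))$shift_ppm, 101,
               tolerance = 1e-12)
  # invariant to a constant energy offset
  expect_equal(boltzmann_average(tri, c(a = 50, b = 50 + gap))$shift_ppm, 101,
               tolerance = 1e-12)
})

test_that("Boltzmann weights sum to one and order does not matter", {
  set.seed(11)
  for (rep in 1:20) {
    k <- sample(2:6, 1)
    e <- stats::runif(k, 0, 30)
    names(e) <- paste0("c", seq_len(k))
    sh <- conformer_table(lapply(setNames(seq_len(k), names(e)), function(i)
      c("C-1" = stats::runif(1, 90, 110), "C-2" = stats::runif(1, 90, 110))))
    avg <- boltzmann_average(sh, e)
    expect_lt(abs(sum(attr(avg, "weights")) - 1), 1e-12)
    perm <- sample(k)
    avg2 <- boltzmann_average(sh, e[perm])
    expect_equal(avg2$shift_ppm, avg$shift_ppm, tolerance = 1e-12)
  }
  # high-temperature limit tends to the unweighted mean
  two <- conformer_table(list(a = c("C-1" = 100), b = c("C-1" = 104)))
  hot <- boltzmann_average(two, c(a = 0, b = 20), temperature = 1e8)
  expect_equal(hot$shift_ppm, 102, tolerance = 1e-4)
})

test_that("mismatched conformer label sets are rejected", {
  bad <- dplyr::bind_rows(
    tibble::tibble(conformer = "a", label = c("C-1", "C-2"),
                   shift_ppm = c(100, 110)),
    tibble::tibble(conformer = "b", label = "C-1", shift_ppm = 101)
  )
  expect_error(boltzmann_average(bad, c(a = 0, b = 0)),
               class = "pyranoshift_validation_error")
})

test_that("correction factors are recovered exactly on noise-free data", {
  exp_t <- make_entry("m1", c("C-1", "C-8", "C-1'", "C-2'", "C-5"),
                      c(160.0, 125.0, 116.0, 127.0, 101.0),
                      c("core_Cq", "core_CH", "pyran_olefinic_1p",
                        "pyran_olefinic_2p", "core_CH"))
  calc_t <- exp_t
  calc_t$kind <- "calculated"
  calc_t$shift_ppm <- exp_t$shift_ppm +
    c(2.9, 2.9, 3.7, -2.8, 0)  # systematic calc - exp discrepancies
  cf <- derive_corrections(exp_t, calc_t)
  off <- setNames(cf$offset_ppm, cf$class)
  expect_equal(unname(off["C1_C8"]), -2.9, tolerance = 1e-12)
  expect_equal(unname(off["C1p"]), -3.7, tolerance = 1e-12)
  expect_equal(unname(off["C2p"]), 2.8, tolerance = 1e-12)
  expect_equal(cf$n[cf$class == "C1_C8"], 2L)
})

test_that("derive_corrections is location-equivariant and warns on empty classes", {
  exp_t <- make_entry("m1", c("C-1", "C-1'"), c(160, 116),
                      c("core_Cq", "pyran_olefinic_1p"))
  calc_t <- exp_t; calc_t$kind <- "calculated"
  cf0 <- derive_corrections(exp_t, calc_t, classes = c("C1_C8", "C1p"))
  shifted <- calc_t
  shifted$shift_ppm[shifted$label == "C-1"] <-
    shifted$shift_ppm[shifted$label == "C-1"] + 1.7
  cf1 <- derive_corrections(exp_t, shifted, classes = c("C1_C8", "C1p"))
  expect_equal(cf1$offset_ppm[cf1$class == "C1_C8"],
               cf0$offset_ppm[cf0$class == "C1_C8"] - 1.7, tolerance = 1e-12)
  expect_warning(
    derive_corrections(exp_t, calc_t, classes = c("C1_C8", "C2p")),
    "C2p"
  )
})

test_that("applying factors adjusts only covered classes, without mutation", {
  entry <- make_entry("c1", c("C-1", "C-2'", "C-5"), c(160.0, 128.0, 101.0),
                      c("core_Cq", "pyran_olefinic_2p", "core_CH"),
                      kind = "calculated")
  before <- entry$shift_ppm
  out <- apply_corrections(entry, default_corrections())
  expect_equal(out$shift_ppm, c(160.0 - 2.9, 128.0 + 2.8, 101.0))
  expect_identical(entry$shift_ppm, before)
  empty <- new_corr <- default_corrections()[0, ]
  expect_equal(apply_corrections(entry, empty)$shift_ppm, before)
  expect_equal(apply_corrections(entry, NULL)$shift_ppm, before)
})

test_that("derived factors zero the class-wise mean residuals on their own set", {
  cfg <- generator_config(n_compounds = 30, noise_sd = 1.0, seed = 7)
  ms <- generate_modeling_set(cfg)
  calc <- ms$calculated
  calc$compound_id <- sub("-calc$", "", calc$compound_id)
  cf <- derive_corrections(ms$experimental, calc)
  corrected <- apply_corrections(calc, cf)
  resid <- dplyr::inner_join(
    dplyr::select(ms$experimental, "compound_id", "label", "carbon_class",
                  exp_ppm = "shift_ppm"),
    dplyr::select(corrected, "compound_id", "label", calc_ppm = "shift_ppm"),
    by = c("compound_id", "label")
  )
  resid$cl <- correction_class(resid$label, resid$carbon_class)
  means <- tapply(resid$exp_ppm - resid$calc_ppm, resid$cl, mean)
  expect_true(all(abs(means) < 1e-9))
})

test_that("class offsets are recovered within estimator tolerance across noise levels", {
  # mean absolute estimation error < 1.5 sigma / sqrt(76) per class
  for (sigma in c(0.5, 2.0)) {
    errs <- sapply(1:10, function(s) {
      cfg <- generator_config(n_compounds = 76, noise_sd = sigma, seed = s)
      ms <- generate_modeling_set(cfg)
      calc <- ms$calculated
      calc$compound_id <- sub("-calc$", "", calc$compound_id)
      cf <- derive_corrections(ms$experimental, calc)
      off <- setNames(cf$offset_ppm, cf$class)
      abs(c(off["C1_C8"] + 2.9, off["C1p"] + 3.7, off["C2p"] - 2.8))
    })
    expect_true(all(rowMeans(errs) < 1.5 * sigma / sqrt(76)))
  }
})

test_that("corrections serialise to JSON and back", {
  cf <- default_corrections()
  path <- withr::local_tempfile(fileext = ".json")
  write_corrections(cf, path)
  back <- read_corrections(path)
  expect_equal(back$class, cf$class)
  expect_identical(back$offset_ppm, cf$offset_ppm)
  expect_equal(back$scope[1], "gathered")
})
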