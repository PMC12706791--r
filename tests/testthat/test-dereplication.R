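ref3 <- function() {
  dplyr::bind_rows(
    make_entry("ref-A", paste0("C-", 1:4), c(100.0, 110.0, 120.0, 130.0),
               name = "alphaxanthone", subtype = "B31"),
    make_entry("ref-B", paste0("C-", 1:4), c(100.4, 110.4, 120.4, 129.6),
               name = "betaxanthone", subtype = "D31"),
    make_entry("ref-C", paste0("C-", 1:4), c(60.0, 70.0, 80.0, 90.0),
               name = "gammaxanthone", subtype = "A20")
  )
}

test_that("every entry retrieves itself at rank 1", {
  coll <- reference_collection(ref3())
  for (id in unique(ref3()$compound_id)) {
    q <- shift_entry(ref3(), id)$shift_ppm
    hits <- search_by_shifts(q, coll, tolerance = 0.01)
    expect_equal(hits$id[1], id)
    expect_equal(hits$n_matched[1], length(q))
    expect_equal(hits$mean_abs_diff[1], 0)
  }
})

test_that("an empty collection yields an empty result, not an error", {
  empty <- reference_collection(demo_collection()[0, ])
  expect_equal(nrow(search_by_shifts(c(100, 110), empty)), 0)
})

test_that("a slightly shifted entry ranks by the exact matching objective", {
  coll <- reference_collection(ref3())
  hits <- search_by_shifts(c(100.0, 110.0, 120.0, 130.0), coll,
                           tolerance = 0.5)
  expect_equal(hits$id, c("ref-A", "ref-B"))
  o <- oracle_match(c(100.0, 110.0, 120.0, 130.0),
                    sort(c(100.4, 110.4, 120.4, 129.6)), 0.5)
  expect_equal(hits$n_matched[hits$id == "ref-B"], o$n_matched)
  expect_equal(hits$mean_abs_diff[hits$id == "ref-B"],
               o$total_diff / o$n_matched, tolerance = 1e-12)
})

test_that("ordered matching equals exhaustive assignment on random instances", {
  set.seed(31)
  for (i in 1:120) {
    m <- sample(1:8, 1); n <- sample(1:8, 1)
    q <- round(stats::runif(m, 95, 105), 2)
    r <- round(stats::runif(n, 95, 105), 2)
    tol <- sample(c(0.3, 1, 3), 1)
    got <- pyranoshift:::match_sorted_shifts(q, r, tol)
    want <- oracle_match(sort(q), sort(r), tol)
    expect_equal(got$n_matched, want$n_matched)
    expect_equal(got$total_diff, want$total_diff, tolerance = 1e-9)
  }
})

test_that("widening the tolerance never loses matches", {
  set.seed(17)
  coll <- reference_collection(ref3())
  q <- stats::runif(5, 95, 135)
  tols <- c(0.1, 0.5, 1, 2, 5, 10)
  counts <- sapply(tols, function(tol) {
    hits <- search_by_shifts(q, coll, tolerance = tol, min_matched = 0)
    sum(hits$n_matched)
  })
  expect_true(all(diff(counts) >= 0))
})

test_that("conflicting literature entries are classified into both modes", {
  # same compound reported twice with a 13 ppm discrepancy at one carbon
  ino <- make_entry("db-1", c("C-4a", "C-8a", "C-9a", "C-9"),
                    c(157.0, 112.0, 103.0, 182.0),
                    name = "inoxanthone-like", subtype = "B31")
  blanco <- make_entry("db-2", c("C-4a", "C-8a", "C-9a", "C-9"),
                       c(144.0, 112.1, 103.1, 182.1),
                       name = "inoxanthone-like", subtype = "B31")
  # distinct structures sharing identical data
  twin1 <- make_entry("db-3", paste0("C-", 1:4), c(100, 110, 120, 130),
                      name = "twin one", subtype = "B31")
  twin2 <- make_entry("db-4", paste0("C-", 1:4), c(100, 110, 120, 130),
                      name = "twin two", subtype = "D31")
  coll <- reference_collection(dplyr::bind_rows(ino, blanco, twin1, twin2))
  conf <- find_conflicts(coll, near_tol = 1.0, min_overlap = 0.9)
  divergent <- conf[conf$conflict == "same_structure_divergent_data", ]
  expect_equal(nrow(divergent), 1)
  expect_setequal(c(divergent$id_a, divergent$id_b), c("db-1", "db-2"))
  identical_pairs <- conf[conf$conflict == "identical_data_distinct_structures", ]
  expect_true(any(identical_pairs$id_a == "db-3" &
                    identical_pairs$id_b == "db-4"))
  # a one-entry collection cannot conflict
  expect_equal(nrow(find_conflicts(reference_collection(ino))), 0)
})

test_that("swapped C-8a / C-9a assignments are detected, clean data are not", {
  a <- make_entry("a", c("C-8a", "C-9a", "C-4a", "C-9"),
                  c(112.8, 103.2, 156.2, 181.0))
  b <- a
  b$compound_id <- "b"
  i8a <- which(b$label == "C-8a"); i9a <- which(b$label == "C-9a")
  b$shift_ppm[c(i8a, i9a)] <- b$shift_ppm[c(i9a, i8a)]
  swaps <- detect_swapped_assignments(a, b)
  expect_equal(nrow(swaps), 1)
  expect_setequal(c(swaps$label_1, swaps$label_2), c("C-8a", "C-9a"))
  # transposing back must explain (almost) the whole discrepancy
  expect_equal(swaps$gain, 2 * abs(112.8 - 103.2), tolerance = 1e-12)

  expect_equal(nrow(detect_swapped_assignments(a, a)), 0)

  # independent small noise offers no transposition worth the gain threshold
  set.seed(2)
  noisy <- a
  noisy$compound_id <- "n"
  noisy$shift_ppm <- noisy$shift_ppm + stats::rnorm(4, 0, 0.2)
  expect_equal(nrow(detect_swapped_assignments(a, noisy)), 0)

  expect_warning(
    detect_swapped_assignments(a, b, candidate_labels = c("C-8a", "C-5")),
    "C-5"
  )
})
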