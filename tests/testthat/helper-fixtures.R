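## In-code fixtures shared across test files.

make_entry <- function(id, labels, shifts, classes = "other",
                       kind = "experimental", subtype = NA_character_,
                       name = NA_character_, intensity = "normal") {
  shift_table(tibble::tibble(
    compound_id = id, name = name, subtype = subtype, kind = kind,
    label = labels, shift_ppm = shifts,
    carbon_class = rep_len(classes, length(labels)),
    intensity = rep_len(intensity, length(labels)),
    solvent = "CDCl3", source = "test"
  ))
}

## Two-compound demo collection used by the I/O round-trip tests.
demo_collection <- function() {
  dplyr::bind_rows(
    make_entry("cmp-1", c("C-9", "C-1'", "C-2'"), c(183.1, 116.0, 127.0),
               c("carbonyl", "pyran_olefinic_1p", "pyran_olefinic_2p"),
               subtype = "B31", name = "demo one"),
    make_entry("cmp-2", c("C-9", "C-2", "OCH3"), c(176.1, 98.0, 56.1),
               c("carbonyl", "core_CH", "methoxy"),
               subtype = "D31", name = "demo two")
  )
}

## Exhaustive bitmask-memoised matching oracle: best (n_matched, total_diff)
## over ALL one-to-one assignments (no sortedness assumption). Independent
## of the package's ordered dynamic program.
oracle_match <- function(q, r, tol) {
  m <- length(q); n <- length(r)
  memo <- new.env(parent = emptyenv())
  rec <- function(i, mask) {
    if (i > m) return(c(0, 0))
    key <- paste0(i, ".", mask)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    best <- rec(i + 1, mask)  # skip q[i]
    for (j in seq_len(n)) {
      bit <- bitwShiftL(1L, j - 1L)
      if (bitwAnd(mask, bit) == 0 && abs(q[i] - r[j]) <= tol) {
        sub <- rec(i + 1, bitwOr(mask, bit))
        cand <- c(sub[1] + 1, sub[2] + abs(q[i] - r[j]))
        if (cand[1] > best[1] ||
            (cand[1] == best[1] && cand[2] < best[2])) {
          best <- cand
        }
      }
    }
    memo[[key]] <- best
    best
  }
  res <- rec(1, 0L)
  list(n_matched = as.integer(res[1]), total_diff = res[2])
}

## Direct (non-log-space) DP4 product oracle.
oracle_dp4 <- function(dev_list, sigma = 2.306, nu = 11.38) {
  lik <- vapply(dev_list, function(d) {
    prod(stats::pt(abs(d$delta) / sigma, df = nu, lower.tail = FALSE))
  }, numeric(1))
  lik / sum(lik)
}
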