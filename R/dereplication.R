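#' Build a reference collection for dereplication
#'
#' Validates a shift table of experimental reference compounds (unique ids)
#' and attaches a sorted shift index per compound. Matching during search is
#' label-free (multisets of ppm values): published assignments are exactly
#' what is under suspicion, so only the values themselves are trusted.
#'
#' @param x A shift table of experimental entries.
#' @return The validated table with class `reference_collection` and a
#'   per-compound sorted index in attribute `"index"`.
#' @export
reference_collection <- function(x) {
  x <- shift_table(x)
  idx <- lapply(split(x$shift_ppm, x$compound_id), sort)
  structure(x, index = idx,
            class = c("reference_collection", class(x)))
}

## Optimal one-to-one matching between two sorted shift vectors under
## |diff| <= tol, maximising matches then minimising total |diff|. Because
## both sequences are sorted and the cost |q - r| satisfies the quadrangle
## inequality, an optimal matching is non-crossing, so an O(mn) dynamic
## program over ordered prefixes is exact.
match_sorted_shifts <- function(q, r, tol) {
  q <- sort(q); r <- sort(r)
  m <- length(q); n <- length(r)
  if (m == 0 || n == 0) return(list(n_matched = 0L, total_diff = 0))
  M <- matrix(0L, m + 1, n + 1)     # matches
  C <- matrix(0, m + 1, n + 1)      # total |diff| of matched pairs
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      best_m <- M[i, j + 1]; best_c <- C[i, j + 1]
      if (M[i + 1, j] > best_m ||
          (M[i + 1, j] == best_m && C[i + 1, j] < best_c)) {
        best_m <- M[i + 1, j]; best_c <- C[i + 1, j]
      }
      d <- abs(q[i] - r[j])
      if (d <= tol) {
        cand_m <- M[i, j] + 1L; cand_c <- C[i, j] + d
        if (cand_m > best_m || (cand_m == best_m && cand_c < best_c)) {
          best_m <- cand_m; best_c <- cand_c
        }
      }
      M[i + 1, j + 1] <- best_m; C[i + 1, j + 1] <- best_c
    }
  }
  list(n_matched = M[m + 1, n + 1], total_diff = C[m + 1, n + 1])
}

#' Search a reference collection by chemical shift values
#'
#' For every collection entry, an exact one-to-one matching between the
#' query shifts and the entry's shifts is computed under the tolerance
#' (maximising matched carbons, then minimising the summed absolute
#' difference). Hits matching fewer than `min_matched` of the query are
#' dropped; the rest rank by matched count (descending), mean absolute
#' difference (ascending), then id.
#'
#' @param query Numeric vector of ppm values (or a single-compound shift
#'   table, whose `shift_ppm` column is used).
#' @param collection A [reference_collection()] (or coercible shift table).
#' @param tolerance Maximum |difference| for a carbon to match, ppm
#'   (default 0.5; literature matches show sub-1-ppm agreement).
#' @param min_matched Minimum matched fraction of the query to report
#'   (default 0.5).
#' @return A tibble of hits: `id`, `n_matched`, `n_query`, `overlap`,
#'   `mean_abs_diff`, `n_unmatched_query`.
#' @export
search_by_shifts <- function(query, collection, tolerance = 0.5,
                             min_matched = 0.5) {
  if (is.data.frame(query)) query <- query$shift_ppm
  stopifnot(length(query) >= 1, tolerance > 0)
  if (!inherits(collection, "reference_collection")) {
    collection <- reference_collection(collection)
  }
  idx <- attr(collection, "index")
  if (length(idx) == 0) {
    return(tibble(id = character(), n_matched = integer(),
                  n_query = integer(), overlap = numeric(),
                  mean_abs_diff = numeric(), n_unmatched_query = integer()))
  }
  q <- sort(query)
  hits <- imap(idx, function(r, id) {
    res <- match_sorted_shifts(q, r, tolerance)
    tibble(
      id = id, n_matched = res$n_matched, n_query = length(q),
      overlap = res$n_matched / length(q),
      mean_abs_diff = if (res$n_matched > 0) res$total_diff / res$n_matched
                      else NA_real_,
      n_unmatched_query = length(q) - res$n_matched
    )
  })
  bind_rows(hits) |>
    filter(.data$overlap >= min_matched) |>
    arrange(desc(.data$n_matched), .data$mean_abs_diff, .data$id)
}

#' Detect duplicate and conflicting entries in a collection
#'
#' Two complementary failure modes seen in the literature are flagged:
#' pairs whose shift multisets coincide (within `near_tol`, at `>=
#' min_overlap` of the larger entry) while their names or subtypes differ
#' (`identical_data_distinct_structures`), and pairs recorded under the
#' same compound name whose data diverge beyond that test
#' (`same_structure_divergent_data`).
#'
#' @param collection A [reference_collection()] with at least 2 entries.
#' @param near_tol Per-carbon match tolerance for "identical" data, ppm
#'   (default 1.0).
#' @param min_overlap Minimum matched fraction of the larger entry
#'   (default 0.9).
#' @return A tibble: `id_a`, `id_b`, `conflict`, `n_matched`, `overlap`,
#'   `mean_abs_diff`. Symmetric pairs are reported once (`id_a < id_b`).
#' @export
find_conflicts <- function(collection, near_tol = 1.0, min_overlap = 0.9) {
  if (!inherits(collection, "reference_collection")) {
    collection <- reference_collection(collection)
  }
  idx <- attr(collection, "index")
  ids <- names(idx)
  meta <- as_tibble(collection) |>
    group_by(.data$compound_id) |>
    summarise(name = first(.data$name), subtype = first(.data$subtype),
              .groups = "drop")
  meta_name <- setNames(meta$name, meta$compound_id)
  meta_subtype <- setNames(meta$subtype, meta$compound_id)
  if (length(ids) < 2) {
    return(tibble(id_a = character(), id_b = character(),
                  conflict = character(), n_matched = integer(),
                  overlap = numeric(), mean_abs_diff = numeric()))
  }
  rows <- list()
  for (i in seq_along(ids)[-length(ids)]) {
    for (j in (i + 1):length(ids)) {
      a <- ids[i]; b <- ids[j]
      res <- match_sorted_shifts(idx[[a]], idx[[b]], near_tol)
      overlap <- res$n_matched / max(length(idx[[a]]), length(idx[[b]]))
      mean_diff <- if (res$n_matched > 0) res$total_diff / res$n_matched
                   else NA_real_
      data_match <- overlap >= min_overlap &&
        !is.na(mean_diff) && mean_diff <= near_tol
      same_structure <- !is.na(meta_name[a]) && !is.na(meta_name[b]) &&
        meta_name[a] == meta_name[b]
      distinct_structure <- !same_structure ||
        (!is.na(meta_subtype[a]) && !is.na(meta_subtype[b]) &&
           meta_subtype[a] != meta_subtype[b])
      cls <- if (data_match && distinct_structure) {
        "identical_data_distinct_structures"
      } else if (!data_match && same_structure) {
        "same_structure_divergent_data"
      } else {
        NA_character_
      }
      if (!is.na(cls)) {
        rows[[length(rows) + 1]] <- tibble(
          id_a = a, id_b = b, conflict = cls,
          n_matched = res$n_matched, overlap = overlap,
          mean_abs_diff = mean_diff
        )
      }
    }
  }
  if (length(rows) == 0) {
    return(tibble(id_a = character(), id_b = character(),
                  conflict = character(), n_matched = integer(),
                  overlap = numeric(), mean_abs_diff = numeric()))
  }
  bind_rows(rows)
}

#' Detect pairwise swapped assignments between two data sets
#'
#' Quaternary carbons with similar shifts (classically C-8a vs C-9a) are
#' frequently interchanged between published data sets of the same
#' compound. For every pair of candidate labels, the function tests whether
#' transposing the pair in `b` reduces the summed absolute difference to
#' `a` over those two labels by at least `gain_tol`; qualifying pairs are
#' reported best-gain first. Only single transpositions are searched --
#' the narrated failure mode -- keeping the scan O(n^2).
#'
#' @param a,b Single-compound shift tables sharing the candidate labels.
#' @param candidate_labels Labels to consider (default: all labels shared
#'   by `a` and `b`). Labels missing from either entry are skipped with a
#'   warning.
#' @param gain_tol Minimum improvement (ppm) to report a swap (default 1.0).
#' @return A tibble (`label_1`, `label_2`, `gain`) sorted by decreasing
#'   gain; zero rows when no transposition helps.
#' @export
detect_swapped_assignments <- function(a, b, candidate_labels = NULL,
                                       gain_tol = 1.0) {
  a <- shift_table(a); b <- shift_table(b)
  av <- setNames(a$shift_ppm, a$label)
  bv <- setNames(b$shift_ppm, b$label)
  if (is.null(candidate_labels)) {
    candidate_labels <- intersect(a$label, b$label)
  } else {
    candidate_labels <- normalize_label(candidate_labels)
    missing <- setdiff(candidate_labels, intersect(names(av), names(bv)))
    if (length(missing)) {
      warn(paste0("label(s) missing from one entry, skipped: ",
                  paste(missing, collapse = ", ")))
      candidate_labels <- setdiff(candidate_labels, missing)
    }
  }
  labs <- unique(candidate_labels)
  if (length(labs) < 2) {
    return(tibble(label_1 = character(), label_2 = character(),
                  gain = numeric()))
  }
  rows <- list()
  for (i in seq_along(labs)[-length(labs)]) {
    for (j in (i + 1):length(labs)) {
      x <- labs[i]; y <- labs[j]
      now <- abs(av[x] - bv[x]) + abs(av[y] - bv[y])
      swapped <- abs(av[x] - bv[y]) + abs(av[y] - bv[x])
      gain <- now - swapped
      if (gain >= gain_tol) {
        rows[[length(rows) + 1]] <- tibble(label_1 = x, label_2 = y,
                                           gain = unname(gain))
      }
    }
  }
  if (length(rows) == 0) {
    return(tibble(label_1 = character(), label_2 = character(),
                  gain = numeric()))
  }
  bind_rows(rows) |> arrange(desc(.data$gain))
}
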