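#' Per-carbon deviations between a calculated candidate and experiment
#'
#' Aligns the two single-compound tables on normalised labels, optionally
#' applies empirical correction factors to the calculated side first, and
#' returns the signed deviation `delta = corrected calculated - experimental`
#' per shared label. Carbons present on only one side are reported in the
#' `excluded` attribute, not silently dropped. A carbon flagged with
#' `intensity = "double"` on the experimental side may serve two calculated
#' labels (one signal legitimately read twice).
#'
#' @param experimental,calculated Single-compound shift tables.
#' @param factors Optional `corrections` tibble applied to `calculated`.
#' @return A tibble (`label`, `carbon_class`, `exp_ppm`, `calc_ppm`,
#'   `delta`) with attributes `excluded` (labels unmatched on either side)
#'   and `n_shared`.
#' @examples
#' \dontrun{
#' shift_deviations(exp_entry, calc_entry, default_corrections())
#' }
#' @export
shift_deviations <- function(experimental, calculated, factors = NULL) {
  exp_t <- shift_table(experimental)
  calc_t <- shift_table(calculated)
  if (length(unique(exp_t$compound_id)) > 1 ||
      length(unique(calc_t$compound_id)) > 1) {
    abort("shift_deviations expects single-compound tables",
          class = "pyranoshift_validation_error")
  }
  if (!is.null(factors)) calc_t <- apply_corrections(calc_t, factors)
  ## a double-intensity experimental signal may be consumed by two labels:
  ## duplicate its row under each calculated label it can serve is handled
  ## naturally by the label join when assignments reuse the label; here the
  ## flag only relaxes the duplicate-label invariant upstream.
  matched <- inner_join(
    exp_t |> select("label", "carbon_class", exp_ppm = "shift_ppm"),
    calc_t |> select("label", calc_ppm = "shift_ppm"),
    by = "label", relationship = "many-to-many"
  )
  if (nrow(matched) == 0) {
    abort("no shared carbon labels between the two entries",
          class = "pyranoshift_alignment_error")
  }
  out <- matched |> mutate(delta = .data$calc_ppm - .data$exp_ppm)
  attr(out, "excluded") <- sort(unique(c(
    setdiff(exp_t$label, calc_t$label), setdiff(calc_t$label, exp_t$label)
  )))
  attr(out, "n_shared") <- nrow(out)
  out
}

#' Deviation summary statistics
#'
#' `shift_rmsd()` is the root-mean-square of the signed deviations;
#' `shift_max_dev()` returns the largest absolute deviation together with
#' its carbon label. Values are never rounded in computation; round only
#' for presentation.
#'
#' @param dev A deviation tibble from [shift_deviations()], or any data
#'   frame with columns `label` and `delta`.
#' @return `shift_rmsd()`: a single number (ppm). `shift_max_dev()`: a
#'   one-row tibble (`label`, `max_dev`).
#' @examples
#' dev <- tibble::tibble(label = c("C-1", "C-2"), delta = c(3, -4))
#' shift_rmsd(dev)
#' shift_max_dev(dev)
#' @export
shift_rmsd <- function(dev) {
  stopifnot(nrow(dev) >= 1)
  sqrt(mean(dev$delta^2))
}

#' @rdname shift_rmsd
#' @export
shift_max_dev <- function(dev) {
  stopifnot(nrow(dev) >= 1)
  i <- which.max(abs(dev$delta))
  tibble(label = dev$label[i], max_dev = abs(dev$delta[i]))
}

#' DP4 candidate probabilities
#'
#' Goodman's DP4: each candidate's likelihood is the product over carbons of
#' the Student-t survival probability of its absolute scaled error,
#' `S_t(|delta| / sigma; nu)`, and probabilities are the likelihoods
#' normalised across candidates. Likelihoods are accumulated in log space,
#' so many-carbon products cannot underflow. Defaults are the published
#' carbon-13 parameters `sigma = 2.306` ppm and `nu = 11.38`.
#'
#' @param deviations A named list of deviation tibbles (one per candidate),
#'   or a single tibble with a `candidate_id` column.
#' @param sigma Student-t scale in ppm.
#' @param nu Student-t degrees of freedom.
#' @return A tibble (`candidate_id`, `log_lik`, `dp4`) in input order;
#'   `dp4` sums to 1.
#' @examples
#' d1 <- tibble::tibble(label = c("C-1", "C-2"), delta = c(1, -1))
#' d2 <- tibble::tibble(label = c("C-1", "C-2"), delta = c(3, 3))
#' dp4_probabilities(list(a = d1, b = d2))
#' @export
dp4_probabilities <- function(deviations, sigma = 2.306, nu = 11.38) {
  stopifnot(sigma > 0, nu > 0)
  if (is.data.frame(deviations)) {
    stopifnot("candidate_id" %in% names(deviations))
    deviations <- split(deviations,
                        factor(deviations$candidate_id,
                               levels = unique(deviations$candidate_id)))
  }
  if (length(deviations) == 0) {
    abort("at least one candidate is required",
          class = "pyranoshift_validation_error")
  }
  ids <- names(deviations) %||% as.character(seq_along(deviations))
  log_lik <- map_dbl(deviations, function(d) {
    stopifnot(nrow(d) >= 1)
    sum(stats::pt(abs(d$delta) / sigma, df = nu,
                  lower.tail = FALSE, log.p = TRUE))
  })
  if (all(!is.finite(log_lik))) {
    abort("all DP4 likelihoods underflowed to -Inf",
          class = "pyranoshift_numeric_error")
  }
  m <- max(log_lik)
  p <- exp(log_lik - m)
  tibble(candidate_id = ids, log_lik = unname(log_lik),
         dp4 = unname(p / sum(p)))
}

#' Flag a lone large deviation
#'
#' A single aberrant deviation amid otherwise well-fitting carbons suggests
#' a typographical error, a misread spectrum or contamination rather than a
#' wrong structure. The largest-|delta| carbon is flagged iff it reaches
#' `t_major` while the second-largest |delta| stays at or below `t_rest`;
#' the RMSD recomputed without it is returned alongside.
#'
#' @param dev A deviation tibble with at least 3 rows.
#' @param t_major Threshold for the outlying deviation (default 5 ppm).
#' @param t_rest Ceiling for all remaining deviations (default 3 ppm).
#' @return `NULL` when no single-outlier pattern is present, otherwise a
#'   one-row tibble (`label`, `delta`, `rmsd_excluding`).
#' @export
flag_single_outlier <- function(dev, t_major = 5, t_rest = 3) {
  stopifnot(nrow(dev) >= 3)
  a <- abs(dev$delta)
  ord <- order(a, decreasing = TRUE)
  if (a[ord[1]] >= t_major && a[ord[2]] <= t_rest) {
    tibble(label = dev$label[ord[1]], delta = dev$delta[ord[1]],
           rmsd_excluding = shift_rmsd(dev[-ord[1], ]))
  } else {
    NULL
  }
}

#' Score and rank candidate structures against an experimental entry
#'
#' For each candidate: corrections are applied (when given), deviations are
#' computed over shared labels, and RMSD, maximum deviation, a DP4
#' probability across the candidate set and a single-outlier flag are
#' assembled. Candidates are ranked by DP4 (descending) with ties broken by
#' lower RMSD then lexicographic candidate id, so the ordering is
#' deterministic.
#'
#' @param experimental A single-compound experimental shift table.
#' @param candidates A shift table holding one or more calculated
#'   candidates (distinct `compound_id`s).
#' @param factors Optional `corrections` applied to every candidate.
#' @param sigma,nu DP4 Student-t parameters (see [dp4_probabilities()]).
#' @param rescale If `TRUE`, candidates are first linearly rescaled against
#'   experiment (regression of calculated on experimental shifts), the
#'   original DP4 formulation; off by default, where the carbon-class
#'   corrections play that role.
#' @param t_major,t_rest Single-outlier thresholds
#'   (see [flag_single_outlier()]).
#' @return A `candidate_ranking` tibble: `candidate_id`, `n_shared`,
#'   `rmsd`, `max_dev`, `max_dev_label`, `dp4`, `outlier_label`,
#'   `rmsd_excluding_outlier`, `rank`. Deviation tibbles are carried in the
#'   `"deviations"` attribute.
#' @export
rank_candidates <- function(experimental, candidates, factors = NULL,
                            sigma = 2.306, nu = 11.38, rescale = FALSE,
                            t_major = 5, t_rest = 3) {
  cand_t <- shift_table(candidates)
  ids <- unique(cand_t$compound_id)
  if (length(ids) == 0) {
    abort("at least one candidate is required",
          class = "pyranoshift_validation_error")
  }
  devs <- lapply(ids, function(id) {
    d <- shift_deviations(experimental, shift_entry(cand_t, id), factors)
    if (rescale) d <- rescale_deviations(d)
    d
  })
  names(devs) <- ids
  dp4 <- dp4_probabilities(devs, sigma = sigma, nu = nu)
  rows <- map2(ids, devs, function(id, d) {
    md <- shift_max_dev(d)
    fl <- if (nrow(d) >= 3) flag_single_outlier(d, t_major, t_rest) else NULL
    tibble(
      candidate_id = id,
      n_shared = nrow(d),
      rmsd = shift_rmsd(d),
      max_dev = md$max_dev,
      max_dev_label = md$label,
      outlier_label = if (is.null(fl)) NA_character_ else fl$label,
      rmsd_excluding_outlier = if (is.null(fl)) NA_real_ else fl$rmsd_excluding
    )
  })
  out <- bind_rows(rows) |>
    left_join(dp4[, c("candidate_id", "dp4")], by = "candidate_id") |>
    arrange(desc(.data$dp4), .data$rmsd, .data$candidate_id) |>
    mutate(rank = row_number()) |>
    select("candidate_id", "rank", "n_shared", "rmsd", "max_dev",
           "max_dev_label", "dp4", "outlier_label", "rmsd_excluding_outlier")
  attr(out, "deviations") <- devs
  class(out) <- c("candidate_ranking", class(out))
  out
}

## Goodman-style linear rescaling: regress calculated on experimental shifts
## and take residuals of the back-transformed values as the new deviations.
rescale_deviations <- function(dev) {
  if (nrow(dev) < 3 || stats::sd(dev$exp_ppm) == 0) return(dev)
  fit <- stats::lm(calc_ppm ~ exp_ppm, data = dev)
  slope <- stats::coef(fit)[["exp_ppm"]]
  intercept <- stats::coef(fit)[["(Intercept)"]]
  if (abs(slope) < 1e-8) return(dev)
  scaled <- (dev$calc_ppm - intercept) / slope
  dev$delta <- scaled - dev$exp_ppm
  dev
}
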