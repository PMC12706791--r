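#' Tidy a candidate ranking
#'
#' @param x A `candidate_ranking` from [rank_candidates()].
#' @param ... Unused.
#' @return The scores as a plain tibble.
#' @method tidy candidate_ranking
#' @export
tidy.candidate_ranking <- function(x, ...) {
  out <- as_tibble(x)
  attr(out, "deviations") <- NULL
  out
}

#' @rdname tidy.candidate_ranking
#' @method glance candidate_ranking
#' @export
glance.candidate_ranking <- function(x, ...) {
  tibble(
    n_candidates = nrow(x),
    top_candidate = x$candidate_id[1],
    top_dp4 = x$dp4[1],
    top_rmsd = x$rmsd[1],
    top_max_dev = x$max_dev[1]
  )
}

#' Tidy a subtype diagnosis
#'
#' @param x A `subtype_diagnosis` from [classify_subtype()].
#' @param ... Unused.
#' @return The subtype ranking as a plain tibble.
#' @method tidy subtype_diagnosis
#' @export
tidy.subtype_diagnosis <- function(x, ...) {
  out <- as_tibble(x)
  attr(out, "matches") <- NULL
  out
}

#' @rdname tidy.subtype_diagnosis
#' @method glance subtype_diagnosis
#' @export
glance.subtype_diagnosis <- function(x, ...) {
  tibble(
    assigned = attr(x, "assigned"),
    top_subtype = x$subtype[1],
    top_frac_matched = x$frac_matched[1],
    top_mean_abs_dev = x$mean_abs_dev[1],
    floor = attr(x, "floor")
  )
}

#' Tidy correction factors
#'
#' @param x A `corrections` tibble.
#' @param ... Unused.
#' @return A plain tibble of the factors.
#' @method tidy corrections
#' @export
tidy.corrections <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- class(tibble())
  out
}

#' Tidy a revision report
#'
#' `tidy()` returns the candidate score table; `glance()` a one-row verdict
#' summary.
#'
#' @param x A `revision_report` from [revise()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy revision_report
#' @export
tidy.revision_report <- function(x, ...) {
  if (is.null(x$scores)) {
    return(tibble(candidate_id = character(), rank = integer(),
                  rmsd = numeric(), max_dev = numeric(), dp4 = numeric()))
  }
  tidy(x$scores)
}

#' @rdname tidy.revision_report
#' @method glance revision_report
#' @export
glance.revision_report <- function(x, ...) {
  tibble(
    entry_id = x$entry_id,
    claimed = x$claimed,
    diagnosed = attr(x$diagnosis, "assigned"),
    n_violations = nrow(x$violations),
    top_candidate = if (is.null(x$scores)) NA_character_
                    else x$scores$candidate_id[1],
    top_dp4 = if (is.null(x$scores)) NA_real_ else x$scores$dp4[1],
    verdict = x$verdict,
    reassign_to = x$reassign_to
  )
}
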