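## Gas constant in kJ/(mol K); conformer energies are accepted in kJ/mol only.
R_KJ <- 8.314e-3

new_corrections <- function(x) {
  x <- as_tibble(x)
  stopifnot(all(c("class", "offset_ppm") %in% names(x)))
  if (!"n" %in% names(x)) x$n <- NA_integer_
  if (!"sd" %in% names(x)) x$sd <- NA_real_
  if (!"scope" %in% names(x)) x$scope <- "gathered"
  structure(x[, c("class", "offset_ppm", "n", "sd", "scope")],
            class = c("corrections", class(tibble())))
}

#' Map a carbon assignment to its empirical-correction class
#'
#' The systematic calculated-vs-experimental discrepancies are tied to three
#' positional roles: the pooled C-1/C-8 core positions flanking the carbonyl
#' (`"C1_C8"`, identified by label), and the two pyran olefinic carbons
#' (`"C1p"`, `"C2p"`, identified by carbon class). All other carbons carry
#' no class correction (`NA`).
#'
#' @param label Character vector of carbon labels (normalised internally).
#' @param carbon_class Character vector of carbon classes.
#' @return Character vector of correction-class tokens or `NA`.
#' @export
correction_class <- function(label, carbon_class) {
  lab <- normalize_label(label)
  dplyr::case_when(
    carbon_class == "pyran_olefinic_1p" ~ "C1p",
    carbon_class == "pyran_olefinic_2p" ~ "C2p",
    lab %in% c("C-1", "C-8") ~ "C1_C8",
    TRUE ~ NA_character_
  )
}

#' Boltzmann-average per-conformer chemical shifts
#'
#' Conformer populations are weighted by `exp(-(E - min E) / (R T))` with
#' energies in kJ/mol, and each carbon's shift is the population-weighted
#' mean across conformers. The result is invariant to adding a constant to
#' all energies; in the high-temperature limit it tends to the unweighted
#' mean.
#'
#' @param shifts A data frame with columns `conformer`, `label`,
#'   `shift_ppm`: the per-conformer shift table. Every conformer must cover
#'   the same label set.
#' @param energies Named (by conformer) or positionally matched numeric
#'   vector of relative conformer energies in kJ/mol.
#' @param temperature Temperature in kelvin (default 298.15).
#' @return A tibble with columns `label`, `shift_ppm` (averaged), carrying
#'   the weights in attribute `"weights"`.
#' @examples
#' sh <- tibble::tibble(conformer = rep(c("a", "b"), each = 1),
#'                      label = "C-1", shift_ppm = c(100, 102))
#' boltzmann_average(sh, energies = c(a = 0, b = 0))
#' @export
boltzmann_average <- function(shifts, energies, temperature = 298.15) {
  shifts <- as_tibble(shifts)
  stopifnot(all(c("conformer", "label", "shift_ppm") %in% names(shifts)))
  if (!all(is.finite(energies))) {
    abort("conformer energies must be finite",
          class = "pyranoshift_validation_error")
  }
  if (temperature <= 0) {
    abort("temperature must be positive",
          class = "pyranoshift_validation_error")
  }
  confs <- unique(shifts$conformer)
  if (is.null(names(energies))) {
    if (length(energies) != length(confs)) {
      abort("energies must be named by conformer or match conformer count",
            class = "pyranoshift_validation_error")
    }
    names(energies) <- confs
  }
  if (!setequal(names(energies), confs)) {
    abort("energy names do not match conformer ids",
          class = "pyranoshift_validation_error")
  }
  label_sets <- split(shifts$label, shifts$conformer)
  ref <- sort(label_sets[[1]])
  same <- vapply(label_sets, function(l) identical(sort(l), ref), logical(1))
  if (!all(same)) {
    abort("conformers do not share an identical label set",
          class = "pyranoshift_validation_error")
  }
  w <- exp(-(energies - min(energies)) / (R_KJ * temperature))
  w <- w / sum(w)
  out <- shifts |>
    mutate(w = unname(w[as.character(.data$conformer)])) |>
    group_by(.data$label) |>
    summarise(shift_ppm = sum(.data$w * .data$shift_ppm), .groups = "drop")
  attr(out, "weights") <- w
  out
}

#' Derive empirical correction factors from matched compound pairs
#'
#' For every experimental/calculated pair, carbons are aligned on normalised
#' labels, each matched carbon is assigned its correction class
#' ([correction_class()]), and the per-class offset is the untrimmed mean of
#' (experimental - calculated) over all matched carbons of that class across
#' the set. Classes with no matched carbons are omitted with a warning
#' rather than zero-filled. Applying the returned factors back to the
#' derivation set makes each class-wise mean residual exactly zero.
#'
#' @param experimental,calculated Shift tables whose `compound_id`s pair up
#'   (every calculated compound id must appear in the experimental table).
#' @param classes Correction classes to derive (default all three).
#' @param scope Scope tag stored with the factors, e.g. `"gathered"` or a
#'   per-type scope like `"type_B"`.
#' @return A `corrections` tibble: `class`, `offset_ppm`, `n`, `sd`, `scope`.
#' @export
derive_corrections <- function(experimental, calculated,
                               classes = c("C1_C8", "C1p", "C2p"),
                               scope = "gathered") {
  exp_t <- shift_table(experimental)
  calc_t <- shift_table(calculated)
  matched <- inner_join(
    exp_t |> select("compound_id", "label", exp_ppm = "shift_ppm",
                    "carbon_class"),
    calc_t |> select("compound_id", "label", calc_ppm = "shift_ppm"),
    by = c("compound_id", "label")
  )
  if (nrow(matched) == 0) {
    abort("no shared labels between experimental and calculated tables",
          class = "pyranoshift_validation_error")
  }
  matched <- matched |>
    mutate(corr_class = correction_class(.data$label, .data$carbon_class)) |>
    filter(.data$corr_class %in% classes)
  missing <- setdiff(classes, unique(matched$corr_class))
  if (length(missing)) {
    warn(paste0("no matched carbons for correction class(es): ",
                paste(missing, collapse = ", "), "; omitted"))
  }
  out <- matched |>
    group_by(class = .data$corr_class) |>
    summarise(
      offset_ppm = mean(.data$exp_ppm - .data$calc_ppm),
      n = n(),
      sd = stats::sd(.data$exp_ppm - .data$calc_ppm),
      .groups = "drop"
    ) |>
    mutate(scope = scope) |>
    arrange(match(.data$class, classes))
  new_corrections(out)
}

#' Apply correction factors to calculated shifts
#'
#' Adds each factor's offset to every calculated shift of its correction
#' class; carbons of classes absent from `factors` pass through unchanged.
#' The input is not mutated.
#'
#' @param x A shift table of calculated entries.
#' @param factors A `corrections` tibble (e.g. [default_corrections()]).
#'   `NULL` or an empty table returns `x` unchanged.
#' @return The corrected shift table.
#' @examples
#' \dontrun{
#' corrected <- apply_corrections(calc_table, default_corrections())
#' }
#' @export
apply_corrections <- function(x, factors) {
  x <- shift_table(x)
  if (is.null(factors) || nrow(factors) == 0) return(x)
  offsets <- setNames(factors$offset_ppm, factors$class)
  cls <- correction_class(x$label, x$carbon_class)
  adj <- ifelse(!is.na(cls) & cls %in% names(offsets),
                unname(offsets[cls]), 0)
  adj[is.na(adj)] <- 0
  x$shift_ppm <- x$shift_ppm + adj
  x
}

#' Read / write correction factors as JSON
#'
#' @param path File path of a corrections document (`class`, `offset_ppm`,
#'   `n`, `sd`, plus a document-level `scope`).
#' @return `read_corrections()` returns a `corrections` tibble;
#'   `write_corrections()` returns `path` invisibly.
#' @export
read_corrections <- function(path) {
  doc <- jsonlite::read_json(path)
  out <- bind_rows(lapply(doc$factors, function(f) {
    tibble(class = f$class, offset_ppm = f$offset_ppm,
           n = f$n %||% NA_integer_, sd = f$sd %||% NA_real_,
           scope = doc$scope %||% "gathered")
  }))
  new_corrections(out)
}

#' @rdname read_corrections
#' @param x A `corrections` tibble.
#' @export
write_corrections <- function(x, path) {
  jsonlite::write_json(list(
    version = "1.0", scope = x$scope[1],
    factors = lapply(seq_len(nrow(x)), function(i) list(
      class = x$class[i], offset_ppm = x$offset_ppm[i],
      n = x$n[i], sd = x$sd[i]
    ))
  ), path, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}

#' @export
print.corrections <- function(x, ...) {
  cat("Empirical 13C correction factors (scope: ", x$scope[1], ")\n", sep = "")
  NextMethod()
}
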