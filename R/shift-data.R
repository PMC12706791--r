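#' Carbon classes recognised in shift tables
#'
#' Closed vocabulary for the `carbon_class` column: aromatic core methines
#' (`core_CH`) and quaternaries (`core_Cq`), the xanthone carbonyl C-9
#' (`carbonyl`), the two olefinic pyran carbons (`pyran_olefinic_1p` for
#' C-1', `pyran_olefinic_2p` for C-2'), the oxygenated core carbon bonded to
#' the pyran oxygen (`pyran_O_Cq`), `methyl`, `methoxy` and `other`.
#'
#' @format Character vector of the nine recognised class tokens.
#' @export
carbon_classes <- c(
  "core_CH", "core_Cq", "carbonyl", "pyran_olefinic_1p",
  "pyran_olefinic_2p", "pyran_O_Cq", "methyl", "methoxy", "other"
)

intensity_notes <- c("normal", "weak", "double")

shift_table_cols <- c(
  "compound_id", "name", "subtype", "kind", "label", "shift_ppm",
  "carbon_class", "intensity", "solvent", "source"
)

#' Normalise carbon position labels
#'
#' Literature assignments write the pyran olefinic carbons variously as
#' C-1'/C-2', C-1''/C-2'' or with typographic primes. Corrections and
#' deviations are keyed to these roles, so labels are normalised before any
#' alignment: typographic primes become ASCII, double primes collapse to a
#' single prime, and internal whitespace is removed.
#'
#' @param label Character vector of carbon labels.
#' @return Character vector of normalised labels.
#' @examples
#' normalize_label(c("C-1′", "C-1''", " C-4a "))
#' @export
normalize_label <- function(label) {
  x <- trimws(label)
  x <- gsub("′|´|`", "'", x)
  x <- gsub("″", "''", x)
  x <- gsub("''", "'", x, fixed = TRUE)
  gsub("[[:space:]]+", "", x)
}

#' Assemble and validate a tidy shift table
#'
#' The package's central container is an ordinary tibble with one row per
#' assigned carbon: `compound_id`, `name`, `subtype`, `kind` (`experimental`
#' or `calculated`), `label`, `shift_ppm`, `carbon_class`, `intensity`,
#' `solvent`, `source`. `shift_table()` fills optional columns, normalises
#' labels and validates.
#'
#' @param x A data frame with at least `compound_id`, `label`, `shift_ppm`
#'   and `carbon_class`.
#' @return A validated tibble with the full column set.
#' @seealso [read_shift_table()], [validate_shift_table()]
#' @export
shift_table <- function(x) {
  x <- as_tibble(x)
  need <- c("compound_id", "label", "shift_ppm", "carbon_class")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols)) {
    abort(paste0("shift table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "pyranoshift_validation_error")
  }
  defaults <- list(name = NA_character_, subtype = NA_character_,
                   kind = "experimental", intensity = "normal",
                   solvent = NA_character_, source = NA_character_)
  for (col in names(defaults)) {
    if (!col %in% names(x)) x[[col]] <- defaults[[col]]
  }
  x$label <- normalize_label(x$label)
  x$shift_ppm <- as.double(x$shift_ppm)
  x$intensity[is.na(x$intensity) | x$intensity == ""] <- "normal"
  x <- x[, shift_table_cols]
  validate_shift_table(x)
}

#' Validate a shift table
#'
#' Checks the container invariants: shifts in (0, 250) ppm, nonempty labels,
#' `carbon_class` and `intensity` from their closed vocabularies, `kind`
#' either experimental or calculated, and no duplicated `(compound_id,
#' label)` pair unless every duplicate is flagged `double` (one
#' double-intensity signal legitimately serving two positions).
#'
#' @param x A shift table.
#' @return The input, invisibly usable in a pipe (returned visibly).
#' @export
validate_shift_table <- function(x) {
  x <- as_tibble(x)
  fail <- function(msg) abort(msg, class = "pyranoshift_validation_error")
  if (nrow(x) == 0) return(x)
  if (any(is.na(x$shift_ppm)) || any(x$shift_ppm <= 0 | x$shift_ppm >= 250)) {
    i <- which(is.na(x$shift_ppm) | x$shift_ppm <= 0 | x$shift_ppm >= 250)[1]
    fail(sprintf("row %d: shift_ppm %s outside (0, 250) ppm",
                 i, format(x$shift_ppm[i])))
  }
  if (any(is.na(x$label) | x$label == "")) {
    fail(sprintf("row %d: empty carbon label", which(x$label == "")[1]))
  }
  bad_class <- setdiff(unique(x$carbon_class), carbon_classes)
  if (length(bad_class)) {
    fail(paste0("unknown carbon_class token(s): ",
                paste(bad_class, collapse = ", ")))
  }
  bad_int <- setdiff(unique(x$intensity), intensity_notes)
  if (length(bad_int)) {
    fail(paste0("unknown intensity note(s): ", paste(bad_int, collapse = ", ")))
  }
  bad_kind <- setdiff(unique(x$kind), c("experimental", "calculated"))
  if (length(bad_kind)) {
    fail(paste0("kind must be experimental or calculated, got: ",
                paste(bad_kind, collapse = ", ")))
  }
  dup <- x |>
    group_by(.data$compound_id, .data$label) |>
    summarise(n = n(), all_double = all(.data$intensity == "double"),
              .groups = "drop") |>
    filter(.data$n > 1, !.data$all_double)
  if (nrow(dup)) {
    fail(sprintf(
      "duplicate label %s in compound %s without a double-intensity flag",
      dup$label[1], dup$compound_id[1]))
  }
  x
}

#' Read a shift-table collection from CSV or JSON
#'
#' CSV uses the flat dialect with header
#' `compound_id,name,subtype,kind,label,shift_ppm,carbon_class,intensity,solvent,source`
#' (UTF-8, `.` decimal separator). JSON stores one document per collection
#' with entries keyed by compound id and shifts as arrays of records with
#' the same field names.
#'
#' @param path File path.
#' @param format `"csv"` or `"json"`; guessed from the extension by default.
#' @return A validated shift table (tibble).
#' @export
read_shift_table <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "csv") {
    raw <- tryCatch(
      readr::read_csv(path, col_types = readr::cols(
        compound_id = readr::col_character(),
        name = readr::col_character(),
        subtype = readr::col_character(),
        kind = readr::col_character(),
        label = readr::col_character(),
        shift_ppm = readr::col_double(),
        carbon_class = readr::col_character(),
        intensity = readr::col_character(),
        solvent = readr::col_character(),
        source = readr::col_character()
      ), progress = FALSE),
      error = function(e) abort(paste0("cannot parse CSV ", path, ": ",
                                       conditionMessage(e)),
                                class = "pyranoshift_parse_error")
    )
    prob <- readr::problems(raw)
    if (nrow(prob)) {
      abort(sprintf("malformed CSV row %d in %s: %s", prob$row[1], path,
                    prob$expected[1]),
            class = "pyranoshift_parse_error")
    }
    shift_table(raw)
  } else {
    doc <- tryCatch(jsonlite::read_json(path),
                    error = function(e) abort(
                      paste0("cannot parse JSON ", path, ": ",
                             conditionMessage(e)),
                      class = "pyranoshift_parse_error"))
    entries <- doc$entries %||% doc
    rows <- imap(entries, function(e, id) {
      shifts <- bind_rows(lapply(e$shifts, as_tibble))
      shifts$compound_id <- id
      shifts$name <- e$name %||% NA_character_
      shifts$subtype <- e$subtype %||% NA_character_
      shifts$kind <- e$kind %||% "experimental"
      shifts$solvent <- e$solvent %||% NA_character_
      shifts$source <- e$source %||% NA_character_
      shifts
    })
    shift_table(bind_rows(rows))
  }
}

#' Write a shift-table collection to CSV or JSON
#'
#' @param x A shift table.
#' @param path Output path.
#' @param format `"csv"` or `"json"`; guessed from the extension by default.
#' @return `path`, invisibly.
#' @export
write_shift_table <- function(x, path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  x <- shift_table(x)
  if (format == "csv") {
    readr::write_csv(x, path, progress = FALSE)
  } else {
    split_x <- split(x, factor(x$compound_id, levels = unique(x$compound_id)))
    entries <- lapply(split_x, function(e) {
      list(
        name = e$name[1], subtype = e$subtype[1], kind = e$kind[1],
        solvent = e$solvent[1], source = e$source[1],
        shifts = lapply(seq_len(nrow(e)), function(i) list(
          label = e$label[i], shift_ppm = e$shift_ppm[i],
          carbon_class = e$carbon_class[i], intensity = e$intensity[i]
        ))
      )
    })
    jsonlite::write_json(list(entries = entries), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, na = "null")
  }
  invisible(path)
}

#' Extract one compound's rows from a shift table
#'
#' @param x A shift table.
#' @param id A compound id present in `x`.
#' @return The single-compound tibble.
#' @export
shift_entry <- function(x, id) {
  out <- filter(as_tibble(x), .data$compound_id == id)
  if (nrow(out) == 0) {
    abort(paste0("no compound with id ", id), class = "pyranoshift_lookup_error")
  }
  out
}
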