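pkg_extdata <- function(file) {
  path <- system.file("extdata", file, package = "pyranoshift")
  if (path == "" || !file.exists(path)) {
    abort(paste0("packaged fixture ", file, " is missing or unreadable"),
          class = "pyranoshift_resource_error")
  }
  path
}

read_fixture <- function(file) {
  tryCatch(jsonlite::read_json(pkg_extdata(file)),
           error = function(e) abort(
             paste0("packaged fixture ", file, " is corrupt: ",
                    conditionMessage(e)),
             class = "pyranoshift_resource_error"))
}

#' Curated registry of revised pyranoxanthone structures
#'
#' Loads the packaged registry of literature pyranoxanthones whose reported
#' structures were found inconsistent with their carbon-13 data: 47 revised
#' entries (R1--R31, with R22 expanding to 17 synthetic derivatives
#' R22a--R22q) plus 5 compounds that could not be reassigned. Six revised
#' entries are flagged as previously unreported natural products.
#'
#' @return A tibble with columns `revision_id`, `original_code`,
#'   `original_name`, `revised_code` (`"unresolved"` when no consistent
#'   structure was found), `revised_name`, `flags` (list-column of character
#'   vectors from `previously_unreported`, `unresolved`,
#'   `single_outlier_noted`) and `parent`.
#' @examples
#' reg <- load_registry()
#' sum(reg$revised_code != "unresolved")
#' @export
load_registry <- function() {
  doc <- read_fixture("registry.json")
  out <- bind_rows(lapply(doc$entries, function(e) {
    tibble(
      revision_id = e$revision_id,
      original_code = e$original_code,
      original_name = e$original_name %||% NA_character_,
      revised_code = e$revised_code,
      revised_name = e$revised_name %||% NA_character_,
      flags = list(unlist(e$flags) %||% character()),
      parent = e$parent %||% NA_character_
    )
  }))
  if (anyDuplicated(out$revision_id)) {
    abort("registry fixture has duplicate revision ids",
          class = "pyranoshift_resource_error")
  }
  unresolved <- out$revised_code == "unresolved"
  if (!all(map_lgl(out$flags[unresolved], ~ "unresolved" %in% .x))) {
    abort("registry fixture inconsistent: unresolved entries must be flagged",
          class = "pyranoshift_resource_error")
  }
  out
}

#' Catalog of the 76-compound modeling set
#'
#' Ids and subtype codes of the modeling set used to derive the empirical
#' correction factors. Compounds with two pyran rings carry dual codes. The
#' catalog holds no shift data; ids not fixed by the source narrative follow
#' the sequential-numbering scheme (see the fixture's `note`).
#'
#' @return A tibble with columns `id`, `name` and `codes` (list-column of
#'   the bare subtype codes in the id).
#' @export
load_modeling_catalog <- function() {
  doc <- read_fixture("modeling_set.json")
  ids <- map_chr(doc$compounds, "id")
  tibble(
    id = ids,
    name = map_chr(doc$compounds, ~ .x$name %||% NA_character_),
    codes = subtype_codes(ids)
  )
}

#' Diagnostic subtype marker table
#'
#' Subtype-specific expected carbon-13 shifts for carbons adjacent to the
#' pyran ring (plus the carbonyl), used by [classify_subtype()] and
#' [check_subtype()]. Values anchored in reported data are tagged
#' `source = "narrative"`; the remainder are implementer interpolations
#' within typical pyranoxanthone ranges.
#'
#' @return A tibble with columns `subtype`, `role`, `label`, `carbon_class`,
#'   `expected_ppm`, `tolerance_ppm`, `source`.
#' @export
load_markers <- function() {
  doc <- read_fixture("markers.json")
  bind_rows(lapply(doc$markers, as_tibble))
}

#' Default empirical correction factors (gathered scope)
#'
#' The packaged carbon-class corrections derived from the 76-compound
#' modeling set: -2.9 ppm for the pooled C-1/C-8 positions, -3.7 ppm for
#' the pyran olefinic C-1' and +2.8 ppm for C-2' (offset = mean
#' experimental minus calculated; applied as calculated + offset).
#' [derive_corrections()] on user data overrides these.
#'
#' @return A `corrections` tibble with columns `class`, `offset_ppm`, `n`,
#'   `sd`, `scope`.
#' @export
default_corrections <- function() {
  doc <- read_fixture("corrections.json")
  out <- bind_rows(lapply(doc$factors, function(f) {
    tibble(class = f$class, offset_ppm = f$offset_ppm,
           n = f$n %||% NA_integer_, sd = f$sd %||% NA_real_,
           scope = doc$scope)
  }))
  new_corrections(out)
}

load_filler_spec <- function() {
  doc <- read_fixture("filler_carbons.json")
  list(
    fillers = bind_rows(lapply(doc$fillers, as_tibble)),
    class_ranges = lapply(doc$class_ranges, unlist),
    subtype_spread = doc$subtype_spread_ppm
  )
}
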