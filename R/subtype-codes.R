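#' Parse pyranoxanthone subtype codes
#'
#' A subtype code is a type letter (A--D, giving the prenylation site C-1 to
#' C-4 of the xanthone core) followed by two digits: the first is the xanthone
#' carbon bonded to the pyran oxygen, the second the position of an extra
#' oxygenated substituent on the ring fused to the pyran (0 when absent).
#' Compounds carrying two pyran rings use a dual code, one segment per ring
#' (e.g. `"B31-19-D32-5"`); each segment may carry a sequential compound
#' number after a hyphen (`"B31-19"`, `"B31-1a"`).
#'
#' @param x Character vector of codes. En/em dashes are treated as hyphens.
#' @return A tibble with one row per pyran ring: `input`, `ring`, `code`
#'   (the bare three-character subtype), `type_letter`, `oxygen_digit`,
#'   `substituent_digit`, `seq_no` (sequential number, `NA` when absent).
#' @examples
#' parse_subtype("B31")
#' parse_subtype("B31-19-D32-5")
#' @export
parse_subtype <- function(x) {
  stopifnot(is.character(x), length(x) >= 1)
  x_norm <- gsub("–|—|‒", "-", trimws(x))
  token_re <- "([A-D])([0-4])([0-4])(-[0-9]+[a-z]?)?"
  full_re <- paste0("^", token_re, "(-", token_re, ")*$")
  bad <- !grepl(full_re, x_norm)
  if (any(bad)) {
    abort(paste0(
      "invalid subtype code(s): ",
      paste(unique(x[bad]), collapse = ", "),
      " (expected letter A-D followed by two digits 0-4, e.g. \"B31\")"
    ), class = "pyranoshift_format_error")
  }
  out <- purrr::map2(x, x_norm, function(orig, s) {
    m <- gregexpr(token_re, s, perl = TRUE)[[1]]
    toks <- regmatches(s, list(m))[[1]]
    tibble(
      input = orig,
      ring = seq_along(toks),
      code = substr(toks, 1, 3),
      type_letter = substr(toks, 1, 1),
      oxygen_digit = as.integer(substr(toks, 2, 2)),
      substituent_digit = as.integer(substr(toks, 3, 3)),
      seq_no = ifelse(nchar(toks) > 3, substring(toks, 5), NA_character_)
    )
  })
  bind_rows(out)
}

#' Format parsed subtype codes back to text
#'
#' Inverse of [parse_subtype()]: one string per distinct `input` group,
#' reassembling dual codes and sequential numbers.
#'
#' @param parsed A tibble as returned by [parse_subtype()].
#' @return Character vector, one element per parsed input.
#' @export
format_subtype <- function(parsed) {
  stopifnot(all(c("code", "ring") %in% names(parsed)))
  key <- if ("input" %in% names(parsed)) parsed$input else "x"
  segs <- ifelse(
    !is.na(parsed$seq_no %||% NA_character_),
    paste0(parsed$code, "-", parsed$seq_no),
    parsed$code
  )
  vapply(
    split(segs[order(match(key, unique(key)), parsed$ring)],
          factor(key, levels = unique(key))),
    paste, collapse = "-", FUN.VALUE = character(1), USE.NAMES = FALSE
  )
}

#' Extract the bare subtype codes contained in compound identifiers
#'
#' @param x Character vector of ids such as `"A23-6"` or `"B31-19-D32-5"`.
#' @return List of character vectors (one per id) of three-character codes.
#' @export
subtype_codes <- function(x) {
  purrr::map(x, function(xi) parse_subtype(xi)$code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
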