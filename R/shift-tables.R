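#' Read a table of chemical-shift sets
#'
#' Parses a delimited table whose header is
#' `label, hybridization, <set_id_1>, <set_id_2>, ...`, one carbon per row.
#' Each set-id column becomes one shift set; column order in the file is
#' preserved and defines the set sequence (for calculated data this is the
#' fixed reference sequence; for experimental data, file order defines the
#' identity permutation). Empty cells are kept as `NA` (an absent assignment,
#' never zero).
#'
#' The delimiter is auto-detected from the extension: `.csv` is
#' comma-separated, `.tsv`/`.tab`/`.txt` tab-separated. Decimal points only;
#' locale decimal commas are not supported.
#'
#' @param path Path to a `.csv` or `.tsv` file.
#' @param origin `"calculated"` or `"experimental"`.
#' @return A `shift_tbl`: a tibble with columns `label`, `hybridization`
#'   (`"sp3"`, `"sp2"` or `"carbonyl"`) and one numeric column per set,
#'   carrying an `origin` attribute.
#' @examples
#' path <- tempfile(fileext = ".csv")
#' writeLines(c("label,hybridization,calc_A,calc_B",
#'              "C1,sp3,23.4,25.1",
#'              "C2,sp2,128.0,126.3"), path)
#' read_shift_table(path, origin = "calculated")
#' @seealso [write_shift_table()], [study_bundle()]
#' @export
read_shift_table <- function(path, origin = c("calculated", "experimental")) {
  origin <- arg_match(origin)
  raw <- read_delim_auto(path)
  if (ncol(raw) < 3L) {
    abort("shift table needs `label`, `hybridization` and at least one set column")
  }
  names(raw)[1:2] <- c("label", "hybridization")
  check_labels_unique(raw$label, path)
  check_hybridization(raw$hybridization, path)
  set_ids <- names(raw)[-(1:2)]
  shifts <- lapply(set_ids, function(id) {
    parse_numeric_column(raw[[id]], column = id, labels = raw$label, path = path)
  })
  names(shifts) <- set_ids
  out <- tibble(label = raw$label, hybridization = raw$hybridization)
  for (id in set_ids) out[[id]] <- shifts[[id]]
  new_shift_tbl(out, origin = origin)
}

#' Write a table of chemical-shift sets
#'
#' Inverse of [read_shift_table()]: writes `label`, `hybridization` and one
#' column per set. Numbers are written at full round-trip precision, so a
#' write-read cycle reproduces every shift bit-identically.
#'
#' @param x A `shift_tbl` (or any data frame in the same layout).
#' @param path Output path; `.csv` writes comma-separated, anything else
#'   tab-separated.
#' @return `path`, invisibly.
#' @export
write_shift_table <- function(x, path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::write_csv(x, path, na = "")
  } else {
    readr::write_tsv(x, path, na = "")
  }
  invisible(path)
}

new_shift_tbl <- function(x, origin) {
  out <- as_tibble(x)
  attr(out, "origin") <- origin
  class(out) <- c("shift_tbl", class(out))
  out
}

#' @export
print.shift_tbl <- function(x, ...) {
  cat(sprintf("# %s shift sets: %d atoms x %d sets\n",
              shift_origin(x), nrow(x), length(set_ids(x))))
  NextMethod()
}

shift_origin <- function(x) attr(x, "origin") %||% "unspecified"

#' Set identifiers of a shift table
#'
#' @param x A `shift_tbl` or a data frame in the same layout.
#' @return Character vector of set-id column names, in table order.
#' @export
set_ids <- function(x) {
  setdiff(names(x), c("label", "hybridization"))
}

#' Shift values of one set as a labelled vector
#'
#' @param x A `shift_tbl`.
#' @param id A set-id column name.
#' @return Named numeric vector (label -> ppm), `NA` for absent assignments.
#' @export
shift_values <- function(x, id) {
  if (!id %in% set_ids(x)) {
    abort(sprintf("no set `%s`; available: %s", id,
                  paste(set_ids(x), collapse = ", ")))
  }
  setNames(x[[id]], x$label)
}

# matrix labels x sets, preserving column order
shift_matrix <- function(x) {
  ids <- set_ids(x)
  m <- as.matrix(x[, ids, drop = FALSE])
  rownames(m) <- x$label
  m
}

PPM_PLAUSIBLE <- c(-20, 250)

check_labels_unique <- function(labels, path = NULL) {
  dup <- unique(labels[duplicated(labels)])
  if (length(dup) > 0L) {
    abort(sprintf("duplicated atom label(s) %s%s",
                  paste0("\"", dup, "\"", collapse = ", "),
                  if (is.null(path)) "" else sprintf(" in %s", path)))
  }
  invisible(labels)
}

HYBRIDIZATIONS <- c("sp3", "sp2", "carbonyl")

check_hybridization <- function(h, path = NULL) {
  bad <- unique(h[!h %in% HYBRIDIZATIONS])
  if (length(bad) > 0L) {
    abort(sprintf(
      "unknown hybridization token(s) %s%s; expected one of %s",
      paste0("\"", bad, "\"", collapse = ", "),
      if (is.null(path)) "" else sprintf(" in %s", path),
      paste(HYBRIDIZATIONS, collapse = ", ")))
  }
  invisible(h)
}

parse_numeric_column <- function(x, column, labels, path) {
  x <- trimws(as.character(x))
  absent <- is.na(x) | x == ""
  val <- suppressWarnings(as.numeric(x))
  bad <- which(!absent & is.na(val))
  if (length(bad) > 0L) {
    abort(sprintf("non-numeric shift value \"%s\" at row %s (atom %s), column %s in %s",
                  x[bad[1]], bad[1], labels[bad[1]], column, path))
  }
  out_of_range <- which(!is.na(val) & (val < PPM_PLAUSIBLE[1] | val > PPM_PLAUSIBLE[2]))
  if (length(out_of_range) > 0L) {
    warn(sprintf("column %s: %d shift value(s) outside the plausible 13C range [%g, %g] ppm",
                 column, length(out_of_range), PPM_PLAUSIBLE[1], PPM_PLAUSIBLE[2]))
  }
  val
}

read_delim_auto <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  readr::read_delim(path, delim = delim, col_types = readr::cols(.default = readr::col_character()),
                    trim_ws = TRUE, progress = FALSE, show_col_types = FALSE)
}
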