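#' Read a conformer ensemble table
#'
#' Parses a delimited table with header
#' `conformer_id, rel_energy, <label_1>, <label_2>, ...`, one conformer per
#' row, each atom column holding that conformer's isotropic shielding (ppm).
#' Relative energies are re-zeroed so the most stable conformer sits at 0;
#' their unit is whatever the upstream program produced and is declared later,
#' when weights are computed (see [boltzmann_weights()]).
#'
#' @param path Path to a `.csv` (comma) or `.tsv` (tab) file.
#' @return A `conformer_tbl`: tibble with columns `conformer_id`,
#'   `rel_energy` and one numeric shielding column per atom label.
#' @examples
#' path <- tempfile(fileext = ".csv")
#' writeLines(c("conformer_id,rel_energy,C1,C2",
#'              "m1,5.0,120.1,35.2",
#'              "m2,3.0,121.3,34.8"), path)
#' read_conformer_table(path)   # energies stored as 2.0 and 0.0
#' @export
read_conformer_table <- function(path) {
  raw <- read_delim_auto(path)
  if (ncol(raw) < 3L) {
    abort("conformer table needs `conformer_id`, `rel_energy` and at least one atom column")
  }
  names(raw)[1:2] <- c("conformer_id", "rel_energy")
  if (anyDuplicated(raw$conformer_id)) {
    abort("duplicated conformer_id in conformer table")
  }
  out <- tibble(conformer_id = raw$conformer_id)
  out$rel_energy <- parse_strict_numeric(raw$rel_energy, "rel_energy", path)
  for (lab in names(raw)[-(1:2)]) {
    out[[lab]] <- parse_strict_numeric(raw[[lab]], lab, path)
  }
  validate_ensemble(out)
  out$rel_energy <- out$rel_energy - min(out$rel_energy)
  class(out) <- c("conformer_tbl", class(out))
  out
}

parse_strict_numeric <- function(x, column, path) {
  x <- trimws(as.character(x))
  val <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(val))
  if (length(bad) > 0L) {
    abort(sprintf("missing or non-numeric value at row %d, column %s in %s: every conformer must cover every atom",
                  bad[1], column, path))
  }
  val
}

ensemble_labels <- function(ensemble) {
  setdiff(names(ensemble), c("conformer_id", "rel_energy"))
}

validate_ensemble <- function(ensemble) {
  if (nrow(ensemble) == 0L) abort("empty conformer ensemble")
  if (!all(c("conformer_id", "rel_energy") %in% names(ensemble))) {
    abort("ensemble needs `conformer_id` and `rel_energy` columns")
  }
  if (any(!is.finite(ensemble$rel_energy))) abort("non-finite conformer energy")
  labs <- ensemble_labels(ensemble)
  if (length(labs) == 0L) abort("ensemble has no atom shielding columns")
  sh <- as.matrix(ensemble[, labs, drop = FALSE])
  if (any(!is.finite(sh))) abort("non-finite shielding value in ensemble")
  invisible(ensemble)
}
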