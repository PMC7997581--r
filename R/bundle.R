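#' Bundle calculated and experimental shift sets for one stereoisomer group
#'
#' Pairs an ordered table of calculated shift sets with an ordered table of
#' experimental ones. The calculated order is the fixed reference sequence
#' (the stereochemistry behind each calculated set is known a priori); the
#' experimental file order defines the identity permutation. All comparisons
#' run on the common atom-label intersection: any label missing (or `NA`)
#' in at least one set is dropped from every comparison with a warning,
#' because the pairwise statistics assume matched carbons and silent
#' zero-filling would corrupt them.
#'
#' @param calc,exp `shift_tbl` tables (see [read_shift_table()]) with the
#'   same number of sets (n >= 2).
#' @return A `study_bundle`: list with elements `calc`, `exp` (the input
#'   tables), `atom_index` (tibble `label`, `hybridization` for the retained
#'   atoms), `labels` (retained labels), `n` (set count per side).
#' @examples
#' fx <- generate_bundle(fixture_spec(n_isomers = 3, n_atoms = 6, seed = 1))
#' fx$bundle
#' @export
study_bundle <- function(calc, exp) {
  for (tbl in list(calc, exp)) {
    if (!all(c("label", "hybridization") %in% names(tbl))) {
      abort("both tables need `label` and `hybridization` columns")
    }
    check_labels_unique(tbl$label)
    check_hybridization(tbl$hybridization)
  }
  n_calc <- length(set_ids(calc))
  n_exp <- length(set_ids(exp))
  if (n_calc != n_exp) {
    abort(sprintf("set counts differ: %d calculated vs %d experimental", n_calc, n_exp))
  }
  if (n_calc < 2L) abort("need at least 2 sets per side")
  shared <- intersect(calc$label, exp$label)
  keep <- shared[vapply(shared, function(l) {
    all(!is.na(calc[calc$label == l, set_ids(calc)])) &&
      all(!is.na(exp[exp$label == l, set_ids(exp)]))
  }, logical(1))]
  dropped <- setdiff(union(calc$label, exp$label), keep)
  if (length(keep) == 0L) abort("no atom label is present in every set")
  if (length(dropped) > 0L) {
    warn(sprintf("dropping %d atom(s) missing from at least one set: %s",
                 length(dropped), paste(dropped, collapse = ", ")))
  }
  atom_index <- calc[match(keep, calc$label), c("label", "hybridization")]
  hyb_exp <- exp$hybridization[match(keep, exp$label)]
  if (!identical(atom_index$hybridization, hyb_exp)) {
    abort("hybridization tags disagree between calculated and experimental tables")
  }
  structure(list(calc = calc, exp = exp, atom_index = as_tibble(atom_index),
                 labels = keep, n = n_calc),
            class = "study_bundle")
}

#' @export
print.study_bundle <- function(x, ...) {
  cat(sprintf("Study bundle: n = %d isomers, %d shared atoms\n", x$n, length(x$labels)))
  cat("  calculated:  ", paste(set_ids(x$calc), collapse = ", "), "\n")
  cat("  experimental:", paste(set_ids(x$exp), collapse = ", "), "\n")
  invisible(x)
}

# label x set matrices restricted to the bundle's shared atoms
bundle_matrices <- function(bundle) {
  list(calc = shift_matrix(bundle$calc)[bundle$labels, , drop = FALSE],
       exp  = shift_matrix(bundle$exp)[bundle$labels, , drop = FALSE])
}
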