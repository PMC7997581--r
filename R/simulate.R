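#' Specification for a synthetic shift-set study
#'
#' Describes a seeded synthetic group of stereoisomer shift sets with a
#' known ground-truth alignment, emulating the structure of real
#' isomer-tetrad studies: a shared carbon skeleton whose per-atom shifts sit
#' in the usual sp3 (10-80 ppm) and sp2 (100-170 ppm) windows, small
#' per-isomer perturbations (the configuration-dependent contrast),
#' experimental measurement noise, and an optional constant calibration
#' offset applied to the calculated side only.
#'
#' @param n_isomers Number of stereoisomers (>= 2); default 4, a tetrad.
#' @param n_atoms Number of carbons (>= 2); default 18.
#' @param sp2_fraction Fraction of sp2 carbons, in `[0, 1]`.
#' @param sp3_range,sp2_range Base-shift ranges (ppm) per hybridization.
#' @param contrast_sd Per-atom, per-isomer perturbation sd (ppm): the
#'   inter-isomer contrast. Default 2.0 ppm, giving typical per-atom
#'   inter-isomer differences of 0-4 ppm as seen in real isomer groups.
#' @param noise_sd Experimental per-atom measurement noise sd (ppm);
#'   default 0.3.
#' @param systematic_offset Constant ppm offset added to every calculated
#'   set, emulating a calibration error; default 0.
#' @param true_permutation `"random"`, or an explicit permutation of
#'   `1:n_isomers` (position k = experimental set index matching the k-th
#'   calculated set).
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_isomers = 4, n_atoms = 18, sp2_fraction = 1/3,
                         sp3_range = c(10, 80), sp2_range = c(100, 170),
                         contrast_sd = 2.0, noise_sd = 0.3,
                         systematic_offset = 0,
                         true_permutation = "random", seed = 1L) {
  check_count(n_isomers, min = 2L)
  check_count(n_atoms, min = 2L)
  if (sp2_fraction < 0 || sp2_fraction > 1) abort("`sp2_fraction` must lie in [0, 1]")
  if (contrast_sd < 0 || noise_sd < 0) abort("standard deviations must be >= 0")
  if (!is.finite(systematic_offset)) abort("`systematic_offset` must be finite")
  if (!identical(true_permutation, "random")) {
    true_permutation <- check_scheme(true_permutation, n_isomers)
  }
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    abort("`seed` must be a single integer")
  }
  structure(list(n_isomers = as.integer(n_isomers), n_atoms = as.integer(n_atoms),
                 sp2_fraction = sp2_fraction, sp3_range = sp3_range,
                 sp2_range = sp2_range, contrast_sd = contrast_sd,
                 noise_sd = noise_sd, systematic_offset = systematic_offset,
                 true_permutation = true_permutation, seed = as.integer(seed)),
            class = "fixture_spec")
}

# run code under a seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic study bundle with known ground truth
#'
#' Draws a base molecule, adds independent per-isomer perturbations
#' (`contrast_sd`) plus the calibration offset to form the calculated sets,
#' then reorders the *offset-free* isomer shifts by the true permutation and
#' adds measurement noise (`noise_sd`) to form the experimental sets.
#' Calculated sets are named `calc_1a`, `calc_1b`, ... (stereochemistry
#' known); experimental sets `exp_u1`, `exp_u2`, ... (assignment unknown).
#'
#' With `noise_sd = 0` and `systematic_offset = 0` under the identity
#' permutation the experimental table equals the calculated one exactly, so
#' the true alignment scores an exact 0.
#'
#' @param spec A [fixture_spec()].
#' @return List with elements `bundle` (a [study_bundle()]),
#'   `true_permutation` (integer scheme) and `spec`.
#' @examples
#' fx <- generate_bundle(fixture_spec(seed = 42))
#' fx$true_permutation
#' rank_alignments(fx$bundle)$best
#' @export
generate_bundle <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(spec$seed, {
    n <- spec$n_isomers
    n_sp2 <- round(spec$n_atoms * spec$sp2_fraction)
    hyb <- c(rep("sp2", n_sp2), rep("sp3", spec$n_atoms - n_sp2))
    base <- ifelse(hyb == "sp2",
                   runif(spec$n_atoms, spec$sp2_range[1], spec$sp2_range[2]),
                   runif(spec$n_atoms, spec$sp3_range[1], spec$sp3_range[2]))
    labels <- paste0("C", seq_len(spec$n_atoms))
    # true (calibration-free) shifts per isomer
    truth <- vapply(seq_len(n), function(k) {
      base + rnorm(spec$n_atoms, 0, spec$contrast_sd)
    }, numeric(spec$n_atoms))
    scheme <- if (identical(spec$true_permutation, "random")) {
      sample(n)
    } else spec$true_permutation
    calc_ids <- paste0("calc_1", letters[seq_len(n)])
    exp_ids <- paste0("exp_u", seq_len(n))
    calc <- tibble(label = labels, hybridization = hyb)
    for (k in seq_len(n)) calc[[calc_ids[k]]] <- truth[, k] + spec$systematic_offset
    exp <- tibble(label = labels, hybridization = hyb)
    expm <- matrix(NA_real_, spec$n_atoms, n)
    for (k in seq_len(n)) {
      expm[, scheme[k]] <- truth[, k] + rnorm(spec$n_atoms, 0, spec$noise_sd)
    }
    for (j in seq_len(n)) exp[[exp_ids[j]]] <- expm[, j]
    list(bundle = study_bundle(new_shift_tbl(calc, "calculated"),
                               new_shift_tbl(exp, "experimental")),
         true_permutation = as.integer(scheme),
         spec = spec)
  })
}

#' Generate a synthetic conformer ensemble
#'
#' Seeded ensemble with an exponential-like spread of relative energies
#' (re-zeroed to the most stable conformer) and smoothly varying per-atom
#' isotropic shieldings around a shared base profile, for exercising the
#' Boltzmann-averaging pipeline without quantum-chemistry output.
#'
#' @param n_conformers,n_atoms Counts (>= 1).
#' @param energy_scale Mean of the energy spread (kcal/mol); default 1.0.
#' @param shielding_sd Per-conformer shielding variation sd (ppm).
#' @param seed Integer seed.
#' @return A `conformer_tbl` (see [read_conformer_table()]).
#' @export
generate_conformer_ensemble <- function(n_conformers, n_atoms,
                                        energy_scale = 1.0,
                                        shielding_sd = 2.0, seed = 1L) {
  check_count(n_conformers, min = 1L)
  check_count(n_atoms, min = 1L)
  with_seed(seed, {
    e <- c(0, rexp(n_conformers - 1L, rate = 1 / energy_scale))
    e <- e - min(e)
    base <- runif(n_atoms, 20, 180)
    out <- tibble(conformer_id = paste0("conf_", seq_len(n_conformers)),
                  rel_energy = e)
    labels <- paste0("C", seq_len(n_atoms))
    for (a in seq_len(n_atoms)) {
      out[[labels[a]]] <- base[a] + rnorm(n_conformers, 0, shielding_sd)
    }
    class(out) <- c("conformer_tbl", class(out))
    out
  })
}

#' Write a synthetic bundle to shift-table files
#'
#' Writes the calculated and experimental tables of a generated bundle in
#' the same dialect [read_shift_table()] reads, plus the ground-truth
#' permutation as JSON, so generated fixtures double as end-to-end demos.
#'
#' @param fx Result of [generate_bundle()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the three paths, invisibly.
#' @export
write_bundle <- function(fx, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(calc = file.path(dir, "calc.csv"),
             exp = file.path(dir, "exp.csv"),
             truth = file.path(dir, "truth.json"))
  write_shift_table(fx$bundle$calc, paths[["calc"]])
  write_shift_table(fx$bundle$exp, paths[["exp"]])
  jsonlite::write_json(list(true_permutation = fx$true_permutation,
                            exp_ids_in_calc_order =
                              set_ids(fx$bundle$exp)[fx$true_permutation]),
                       paths[["truth"]], auto_unbox = FALSE, digits = NA)
  invisible(paths)
}
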