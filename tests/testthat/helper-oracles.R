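# Independent brute-force oracles, written against raw matrices only.
# They deliberately share no code with the package internals.

oracle_mae <- function(a, b) {
  s <- 0
  for (i in seq_along(a)) s <- s + abs(a[i] - b[i])
  s / length(a)
}

oracle_rmsd <- function(a, b) {
  s <- 0
  for (i in seq_along(a)) s <- s + (a[i] - b[i])^2
  sqrt(s / length(a))
}

# calc_m, exp_m: atoms x n matrices; scheme: permutation, position k = exp
# column aligned to calc column k. Triple loop over pairs and atoms.
oracle_mae_dddelta <- function(calc_m, exp_m, scheme) {
  n <- ncol(calc_m)
  total <- 0
  count <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      for (a in seq_len(nrow(calc_m))) {
        dcalc <- calc_m[a, i] - calc_m[a, j]
        dexp <- exp_m[a, scheme[i]] - exp_m[a, scheme[j]]
        total <- total + abs(dcalc - dexp)
        count <- count + 1
      }
    }
  }
  total / count
}

oracle_avg_mae <- function(calc_m, exp_m, scheme) {
  vals <- numeric(ncol(calc_m))
  for (k in seq_len(ncol(calc_m))) {
    vals[k] <- oracle_mae(calc_m[, k], exp_m[, scheme[k]])
  }
  mean(vals)
}

# build a shift table (plain tibble in the package's layout) from a matrix
as_shift_tbl <- function(m, ids, hyb = NULL) {
  n_atoms <- nrow(m)
  out <- tibble::tibble(
    label = paste0("C", seq_len(n_atoms)),
    hybridization = hyb %||% rep(c("sp3", "sp2"), length.out = n_atoms))
  for (k in seq_along(ids)) out[[ids[k]]] <- m[, k]
  out
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# random calc/exp matrix pair in a realistic shift range
random_pair_matrices <- function(n_sets, n_atoms) {
  base <- runif(n_atoms, 10, 170)
  calc_m <- sapply(seq_len(n_sets), function(k) base + rnorm(n_atoms, 0, 2))
  exp_m <- sapply(seq_len(n_sets), function(k) base + rnorm(n_atoms, 0, 2))
  list(calc = matrix(calc_m, n_atoms), exp = matrix(exp_m, n_atoms))
}

random_bundle_from_matrices <- function(m) {
  n <- ncol(m$calc)
  stereomatch::study_bundle(
    as_shift_tbl(m$calc, paste0("calc_", letters[1:n])),
    as_shift_tbl(m$exp, paste0("exp_", seq_len(n))))
}

# tetrad whose exp_1 lies between the a and b predictions but closer to b:
# per-set MAE then prefers calc_b for BOTH exp_1 and exp_2, while every
# pairwise difference set still favours the identity alignment.
ambiguous_tetrad <- function(seed, n_atoms = 18) {
  set.seed(seed)
  base <- runif(n_atoms, 10, 170)
  iso <- sapply(1:4, function(k) base + rnorm(n_atoms, 0, 2))
  exp_m <- iso + matrix(rnorm(n_atoms * 4, 0, 0.05), n_atoms)
  exp_m[, 1] <- 0.4 * iso[, 1] + 0.6 * iso[, 2] + rnorm(n_atoms, 0, 0.05)
  stereomatch::study_bundle(
    as_shift_tbl(iso, paste0("calc_", letters[1:4])),
    as_shift_tbl(exp_m, paste0("exp_", 1:4)))
}
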