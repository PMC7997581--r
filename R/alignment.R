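# --- combinatorics ---------------------------------------------------------

#' Number of comparison alignments for n stereoisomers
#'
#' With the calculated sequence fixed, every ordering of the n experimental
#' sets is one comparison alignment, giving n! schemes (2, 6 and 24 for
#' n = 2, 3, 4).
#'
#' @param n Number of isomer sets per side (>= 1).
#' @return n! as a numeric count.
#' @export
count_alignments <- function(n) {
  check_count(n, min = 1L)
  factorial(n)
}

#' Number of shift-difference sets per alignment
#'
#' Each alignment compares every unordered pair of sets, giving
#' n(n-1)/2 calculated/experimental difference-set pairs (3 for n = 3,
#' 6 for n = 4).
#'
#' @param n Number of isomer sets per side (>= 2).
#' @return n(n-1)/2 as a numeric count.
#' @export
count_pairs <- function(n) {
  check_count(n, min = 2L)
  n * (n - 1) / 2
}

check_count <- function(n, min) {
  if (!is.numeric(n) || length(n) != 1L || n != round(n) || n < min) {
    abort(sprintf("`n` must be a single integer >= %d", min))
  }
  invisible(n)
}

#' Enumerate every comparison alignment
#'
#' All n! permutations of the experimental positions, in deterministic
#' lexicographic order with the identity first. Position k of a scheme names
#' the experimental set (1-based index) aligned to the k-th calculated set.
#'
#' @param n Number of isomer sets per side (>= 2).
#' @return List of integer permutations of `1:n`.
#' @examples
#' enumerate_alignments(3)[1:2]   # identity first, then 1 3 2
#' @export
enumerate_alignments <- function(n) {
  check_count(n, min = 2L)
  perms_lex(seq_len(n))
}

# lexicographic permutations of a sorted integer vector
perms_lex <- function(v) {
  if (length(v) == 1L) return(list(v))
  out <- vector("list", factorial(length(v)))
  k <- 1L
  for (i in seq_along(v)) {
    rest <- perms_lex(v[-i])
    for (r in rest) {
      out[[k]] <- c(v[i], r)
      k <- k + 1L
    }
  }
  out
}

# --- pairwise difference sets ---------------------------------------------

#' Shift differences for every unordered pair of sets
#'
#' For an ordered group of same-origin shift sets, computes the per-atom
#' signed difference \eqn{\delta_i - \delta_j} for every unordered pair
#' i < j, over the common non-missing label intersection. These are the
#' \eqn{\Delta\delta_{calc}} (or \eqn{\Delta\delta_{exp}}) sets the joint
#' alignment score is built from.
#'
#' @param x A `shift_tbl` with >= 2 set columns.
#' @return Tibble with columns `i`, `j` (1-based set positions, i < j),
#'   `set_i`, `set_j`, `label`, `delta` (ppm, signed).
#' @export
pair_difference_sets <- function(x) {
  ids <- set_ids(x)
  if (length(ids) < 2L) abort("need at least 2 sets")
  m <- shift_matrix(x)
  keep <- rowSums(is.na(m)) == 0L
  m <- m[keep, , drop = FALSE]
  if (nrow(m) == 0L) abort("empty common atom-label intersection across sets")
  pairs <- utils::combn(length(ids), 2L)
  purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    d <- unname(m[, a] - m[, b])  # computed up front: tibble() columns `i`,
                                  # `j` would otherwise mask the indices
    tibble(i = a, j = b, set_i = ids[a], set_j = ids[b],
           label = rownames(m), delta = d)
  })
}

#' Double shift difference between a calculated and an experimental pair
#'
#' \eqn{\Delta\Delta\delta = |\Delta\delta_{calc} - \Delta\delta_{exp}|}
#' per atom: the per-atom disagreement between how two calculated sets
#' differ and how the two aligned experimental sets differ. Taking a
#' difference of differences cancels any constant systematic error in
#' either group.
#'
#' @param calc_pair,exp_pair Tibbles with columns `label`, `delta`, as one
#'   pair's rows from [pair_difference_sets()] or from [delta_shift()].
#' @return Tibble `label`, `dd_delta` (ppm, non-negative).
#' @export
dd_delta <- function(calc_pair, exp_pair) {
  if (!setequal(calc_pair$label, exp_pair$label) ||
      nrow(calc_pair) != nrow(exp_pair)) {
    abort("calculated and experimental pairs must cover the same atom labels")
  }
  e <- exp_pair$delta[match(calc_pair$label, exp_pair$label)]
  tibble(label = calc_pair$label, dd_delta = abs(calc_pair$delta - e))
}

# --- alignment scoring -----------------------------------------------------

# core: matrices (labels x n sets, same rows), scheme = integer permutation.
# For each unordered pair i<j, DDdelta = |(C_i - C_j) - (E_perm[i] - E_perm[j])|;
# MAE_DDdelta is the mean over all pairs and labels.
mae_dddelta_core <- function(calc_m, exp_m, scheme) {
  n <- ncol(calc_m)
  ep <- exp_m[, scheme, drop = FALSE]
  total <- 0
  n_terms <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      dd <- abs((calc_m[, i] - calc_m[, j]) - (ep[, i] - ep[, j]))
      total <- total + sum(dd)
      n_terms <- n_terms + length(dd)
    }
  }
  list(mae_dddelta = total / n_terms, n_terms = n_terms)
}

check_scheme <- function(scheme, n) {
  if (!is.numeric(scheme) || length(scheme) != n ||
      !setequal(scheme, seq_len(n))) {
    abort(sprintf("`scheme` must be a permutation of 1:%d", n))
  }
  as.integer(scheme)
}

# shared entry: align two shift tables on their common complete labels
alignment_matrices <- function(calc, exp) {
  n <- length(set_ids(calc))
  if (n != length(set_ids(exp))) {
    abort("calculated and experimental tables must hold the same number of sets")
  }
  if (n < 2L) abort("need at least 2 sets per side")
  cm <- shift_matrix(calc)
  em <- shift_matrix(exp)
  labs <- intersect(rownames(cm)[rowSums(is.na(cm)) == 0L],
                    rownames(em)[rowSums(is.na(em)) == 0L])
  if (length(labs) == 0L) abort("empty common atom-label intersection")
  list(calc = cm[labs, , drop = FALSE], exp = em[labs, , drop = FALSE],
       labels = labs, n = n)
}

#' Score one comparison alignment with MAE of double shift differences
#'
#' Reorders the experimental sets by `scheme`, computes
#' \eqn{\Delta\delta_{calc}} and \eqn{\Delta\delta_{exp}} for every
#' unordered pair of positions, and averages all
#' \eqn{\Delta\Delta\delta = |\Delta\delta_{calc} - \Delta\delta_{exp}|}
#' values over the n(n-1)/2 pairs and all shared atoms.
#'
#' @param calc,exp `shift_tbl` tables with the same number of sets.
#' @param scheme Integer permutation of `1:n`; position k gives the
#'   experimental set aligned to the k-th calculated set.
#' @return One-row tibble: `mae_dddelta` (ppm), `n_terms` (number of
#'   \eqn{\Delta\Delta\delta} values averaged, = n(n-1)/2 x atom count),
#'   `scheme` (list column).
#' @examples
#' fx <- generate_bundle(fixture_spec(n_isomers = 3, n_atoms = 8, seed = 11))
#' mae_dddelta(fx$bundle$calc, fx$bundle$exp, scheme = fx$true_permutation)
#' @export
mae_dddelta <- function(calc, exp, scheme) {
  am <- alignment_matrices(calc, exp)
  scheme <- check_scheme(scheme, am$n)
  res <- mae_dddelta_core(am$calc, am$exp, scheme)
  tibble(mae_dddelta = res$mae_dddelta, n_terms = res$n_terms,
         scheme = list(scheme))
}

#' Average per-set MAE of one comparison alignment
#'
#' The alternative (calibration-sensitive) alignment score: the mean of the
#' n one-vs-one [mae()] values along the aligned positions,
#' \eqn{\mathrm{mean}_k\, MAE(calc_k, exp_{scheme[k]})}.
#'
#' @inheritParams mae_dddelta
#' @return A single ppm value.
#' @export
avg_mae_per_alignment <- function(calc, exp, scheme) {
  am <- alignment_matrices(calc, exp)
  scheme <- check_scheme(scheme, am$n)
  mean(vapply(seq_len(am$n), function(k) {
    mean(abs(am$calc[, k] - am$exp[, scheme[k]]))
  }, numeric(1)))
}

#' Rank every comparison alignment of a study bundle
#'
#' The joint assignment method: enumerate all n! permutations aligning the
#' experimental sets to the fixed calculated sequence, score each with
#' [mae_dddelta()] (and optionally [avg_mae_per_alignment()]), and sort
#' ascending. The lowest \eqn{MAE_{\Delta\Delta\delta}} indicates the best
#' calculated-to-experimental correspondence. Ties within `tie_tol` are
#' reported, never broken silently; display order among ties is the
#' lexicographic enumeration order (identity first).
#'
#' @param bundle A [study_bundle()].
#' @param metrics Metrics to compute: subset of
#'   `c("mae_dddelta", "avg_mae")`. Ranking always sorts by `mae_dddelta`.
#' @param max_sets Safety ceiling on n (n! schemes are enumerated
#'   exhaustively; the default ceiling 8 means at most 40320 schemes).
#' @param tie_tol Absolute ppm tolerance for declaring tied alignments.
#' @return An `alignment_ranking` object; see [tidy()] and [glance()]
#'   methods. Its `scores` tibble has one row per scheme with `rank`,
#'   `alignment` (experimental ids in calculated order), `mae_dddelta`,
#'   optional `avg_mae`, `n_terms` and `tie`.
#' @examples
#' fx <- generate_bundle(fixture_spec(n_isomers = 4, n_atoms = 18, seed = 5))
#' rk <- rank_alignments(fx$bundle)
#' rk
#' glance(rk)
#' @export
rank_alignments <- function(bundle, metrics = c("mae_dddelta", "avg_mae"),
                            max_sets = 8, tie_tol = 1e-9) {
  stopifnot(inherits(bundle, "study_bundle"))
  metrics <- match.arg(metrics, c("mae_dddelta", "avg_mae"), several.ok = TRUE)
  n <- bundle$n
  if (n > max_sets) {
    abort(sprintf(paste("n = %d would enumerate %s schemes; raise `max_sets`",
                        "explicitly if this is intended"), n,
                  format(factorial(n), big.mark = ",")))
  }
  m <- bundle_matrices(bundle)
  schemes <- enumerate_alignments(n)
  exp_ids <- set_ids(bundle$exp)
  scored <- purrr::map_dfr(schemes, function(s) {
    res <- mae_dddelta_core(m$calc, m$exp, s)
    tibble(scheme = list(as.integer(s)),
           alignment = paste(exp_ids[s], collapse = " "),
           mae_dddelta = res$mae_dddelta, n_terms = res$n_terms)
  })
  if ("avg_mae" %in% metrics) {
    scored$avg_mae <- vapply(schemes, function(s) {
      mean(vapply(seq_len(n), function(k) {
        mean(abs(m$calc[, k] - m$exp[, s[k]]))
      }, numeric(1)))
    }, numeric(1))
  }
  ord <- order(scored$mae_dddelta)  # stable: enumeration order breaks ties
  scored <- scored[ord, ]
  scored$rank <- seq_len(nrow(scored))
  best_val <- scored$mae_dddelta[1]
  scored$tie <- scored$mae_dddelta <= best_val + tie_tol
  n_tied <- sum(scored$tie)
  scored$tie <- scored$tie & n_tied > 1L
  structure(list(
    scores = scored,
    best = scored$scheme[[1]],
    best_alignment = scored$alignment[1],
    ties = if (n_tied > 1L) scored$scheme[seq_len(n_tied)] else list(),
    gap = if (nrow(scored) > 1L) scored$mae_dddelta[2] - best_val else NA_real_,
    n = n, labels = bundle$labels,
    calc_ids = set_ids(bundle$calc), exp_ids = exp_ids,
    metrics = metrics, tie_tol = tie_tol
  ), class = "alignment_ranking")
}

#' @export
print.alignment_ranking <- function(x, n = 10, ...) {
  cat(sprintf("Alignment ranking: %d sets, %d atoms, %d schemes\n",
              x$n, length(x$labels), nrow(x$scores)))
  cat(sprintf("  calculated sequence: %s\n", paste(x$calc_ids, collapse = " ")))
  cat(sprintf("  best alignment:      %s  (MAE_DDdelta = %.4f ppm%s)\n",
              x$best_alignment, x$scores$mae_dddelta[1],
              if (length(x$ties) > 0L) sprintf(", %d-way tie", length(x$ties)) else ""))
  if (is.finite(x$gap %||% NA)) {
    cat(sprintf("  gap to second-best:  %.4f ppm\n", x$gap))
  }
  show <- utils::head(x$scores[, setdiff(names(x$scores), "scheme")], n)
  print(as.data.frame(show), row.names = FALSE, digits = 5)
  if (nrow(x$scores) > n) cat(sprintf("  ... %d more schemes\n", nrow(x$scores) - n))
  invisible(x)
}
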