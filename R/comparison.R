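# --- one-vs-one set statistics -------------------------------------------

# Pull two aligned shift vectors over the common non-NA label intersection.
aligned_pair <- function(a, b, a_set = NULL, b_set = NULL) {
  a_set <- a_set %||% single_set_id(a)
  b_set <- b_set %||% single_set_id(b)
  va <- shift_values(a, a_set)
  vb <- shift_values(b, b_set)
  labs <- intersect(names(va)[!is.na(va)], names(vb)[!is.na(vb)])
  if (length(labs) == 0L) abort("empty atom-label intersection between the two sets")
  list(a = va[labs], b = vb[labs], labels = labs,
       a_set = a_set, b_set = b_set)
}

single_set_id <- function(x) {
  ids <- set_ids(x)
  if (length(ids) != 1L) {
    abort(sprintf("table holds %d sets (%s); name one explicitly",
                  length(ids), paste(ids, collapse = ", ")))
  }
  ids
}

#' Per-atom shift differences between a calculated and an experimental set
#'
#' The classic \eqn{\Delta\delta = \delta_{calc} - \delta_{exp}} per matched
#' carbon, kept signed (downstream statistics take the absolute value where
#' they need it).
#'
#' @param calc,exp `shift_tbl` tables.
#' @param calc_set,exp_set Set-id columns to compare; may be omitted when a
#'   table holds a single set.
#' @return Tibble with columns `label`, `delta` (ppm, signed) over the
#'   common non-missing label intersection.
#' @export
delta_shift <- function(calc, exp, calc_set = NULL, exp_set = NULL) {
  p <- aligned_pair(calc, exp, calc_set, exp_set)
  tibble(label = p$labels, delta = unname(p$a - p$b))
}

#' Mean absolute error between two shift sets
#'
#' \eqn{MAE = \sum |\Delta\delta| / n} over the matched carbons.
#'
#' @inheritParams delta_shift
#' @return A single ppm value.
#' @export
mae <- function(calc, exp, calc_set = NULL, exp_set = NULL) {
  p <- aligned_pair(calc, exp, calc_set, exp_set)
  mean(abs(p$a - p$b))
}

#' Root-mean-square deviation between two shift sets
#'
#' \eqn{RMSD = \sqrt{\sum \Delta\delta^2 / n}}; used as a set-similarity
#' diagnostic (near-identical isomer shift sets show RMSDs well under the
#' per-set prediction error, which is what makes one-vs-one ranking
#' ambiguous).
#'
#' @inheritParams delta_shift
#' @param a,b `shift_tbl` tables.
#' @param a_set,b_set Set-id columns to compare.
#' @return A single ppm value.
#' @export
rmsd_between_sets <- function(a, b, a_set = NULL, b_set = NULL) {
  p <- aligned_pair(a, b, a_set, b_set)
  sqrt(mean((p$a - p$b)^2))
}

#' Pairwise RMSD summary over a group of shift sets
#'
#' Computes [rmsd_between_sets()] for every unordered pair of sets in one
#' table and summarises the spread: a small average RMSD means the isomer
#' sets are hard to tell apart.
#'
#' @param x A `shift_tbl` with at least two set columns.
#' @return One-row tibble: `average`, `min`, `max` (ppm) and `n_pairs`.
#' @export
rmsd_summary <- function(x) {
  ids <- set_ids(x)
  if (length(ids) < 2L) abort("need at least 2 sets for a pairwise RMSD summary")
  pairs <- utils::combn(ids, 2L)
  vals <- apply(pairs, 2L, function(p) rmsd_between_sets(x, x, p[1], p[2]))
  tibble(average = mean(vals), min = min(vals), max = max(vals),
         n_pairs = ncol(pairs))
}

# --- classic one-experimental-vs-all-calculated ranking -------------------

#' Classic per-set ranking of calculated candidates for each experimental set
#'
#' The traditional workflow: each experimental set is compared separately
#' against every calculated set, and for each experimental set the
#' best-scoring calculated candidate is flagged. Ties (within `tie_tol`) are
#' flagged, never silently broken -- with near-identical isomers this
#' ranking is exactly where ambiguity arises (the same calculated set can
#' win for two different experimental sets), which is what the joint
#' permutation ranking of [rank_alignments()] resolves.
#'
#' @param bundle A [study_bundle()].
#' @param metric `"mae"`, `"rmsd"` (lower is better) or `"probability"`
#'   (DP4-style, higher is better; requires `params`).
#' @param params A [probability_params()] object, required for
#'   `metric = "probability"`.
#' @param tie_tol Absolute tolerance for declaring tied scores.
#' @return A `classic_ranking` object; its `scores` tibble has one row per
#'   (experimental, calculated) pair with `score`, `best` and `tie` flags.
#' @examples
#' fx <- generate_bundle(fixture_spec(n_isomers = 3, n_atoms = 10, seed = 4))
#' classic_ranking(fx$bundle)
#' @export
classic_ranking <- function(bundle, metric = c("mae", "rmsd", "probability"),
                            params = NULL, tie_tol = 1e-9) {
  metric <- arg_match(metric)
  stopifnot(inherits(bundle, "study_bundle"))
  calc_ids <- set_ids(bundle$calc)
  exp_ids <- set_ids(bundle$exp)
  grid <- tidyr::expand_grid(exp_id = exp_ids, calc_id = calc_ids)
  if (metric == "probability") {
    if (is.null(params)) {
      abort(paste("metric = \"probability\" needs `params`:",
                  "supply published error-distribution parameters via probability_params()"))
    }
    score_by_exp <- lapply(exp_ids, function(e) {
      deltas <- lapply(calc_ids, function(cid) {
        delta_shift(bundle$calc, bundle$exp, cid, e)
      })
      names(deltas) <- calc_ids
      p <- dp4_style_probability(deltas, params)
      p$probability[match(calc_ids, p$candidate)]
    })
    grid$score <- unlist(score_by_exp)
    better <- function(s) s > max(s) - tie_tol
  } else {
    fun <- if (metric == "mae") mae else rmsd_between_sets
    grid$score <- purrr::map2_dbl(grid$exp_id, grid$calc_id, function(e, cid) {
      fun(bundle$calc, bundle$exp, cid, e)
    })
    better <- function(s) s < min(s) + tie_tol
  }
  scores <- grid %>%
    group_by(.data$exp_id) %>%
    mutate(best = better(.data$score),
           tie = sum(better(.data$score)) > 1L) %>%
    ungroup()
  structure(list(scores = scores, metric = metric,
                 calc_ids = calc_ids, exp_ids = exp_ids,
                 labels = bundle$labels, tie_tol = tie_tol),
            class = "classic_ranking")
}

#' @export
print.classic_ranking <- function(x, ...) {
  wide <- tidyr::pivot_wider(x$scores[, c("exp_id", "calc_id", "score")],
                             names_from = "calc_id", values_from = "score")
  cat(sprintf("Classic per-set ranking (metric: %s, %d atoms)\n",
              x$metric, length(x$labels)))
  print(as.data.frame(wide), row.names = FALSE)
  best <- x$scores[x$scores$best, ]
  for (e in x$exp_ids) {
    b <- best[best$exp_id == e, ]
    cat(sprintf("  %s -> %s%s\n", e, paste(b$calc_id, collapse = " / "),
                if (any(b$tie)) "  [tie]" else ""))
  }
  dup <- best %>% group_by(.data$calc_id) %>%
    summarise(k = dplyr::n_distinct(.data$exp_id)) %>% filter(.data$k > 1L)
  if (nrow(dup) > 0L) {
    cat("  note: the same calculated set wins for multiple experimental sets;\n",
        " the per-set ranking is ambiguous -- see rank_alignments()\n", sep = "")
  }
  invisible(x)
}

# --- DP4-style probability backend ----------------------------------------

#' Error-distribution parameters for the DP4-style backend
#'
#' Location-scale t-distribution parameters for calculated-shift errors.
#' These belong to published calibrations (Goodman's DP4, Sarotti's DP4+)
#' and are deliberately user-supplied; the backend itself is a generic
#' single-component t-density, not a re-implementation of either method.
#'
#' @param degrees_of_freedom Positive degrees of freedom of the t density.
#' @param location Error mean (ppm).
#' @param scale Error standard-deviation parameter (ppm), > 0.
#' @return A `probability_params` list.
#' @export
probability_params <- function(degrees_of_freedom, location = 0, scale) {
  if (!is.numeric(degrees_of_freedom) || degrees_of_freedom <= 0) {
    abort("`degrees_of_freedom` must be > 0")
  }
  if (!is.numeric(scale) || scale <= 0) abort("`scale` must be > 0")
  if (!is.finite(location)) abort("`location` must be finite")
  structure(list(degrees_of_freedom = degrees_of_freedom,
                 location = location, scale = scale),
            class = "probability_params")
}

#' DP4-style candidate probabilities from shift-error sets
#'
#' Scores each candidate's per-atom errors with a location-scale
#' t-likelihood and normalises across candidates, so the probabilities sum
#' to 1. Likelihoods are accumulated in log space.
#'
#' @param deltas_by_candidate Named list of per-candidate error tables, each
#'   a tibble with columns `label`, `delta` (as from [delta_shift()]), or a
#'   single long tibble with columns `candidate`, `label`, `delta`.
#' @param params A [probability_params()] object with published distribution
#'   parameters.
#' @return Tibble `candidate`, `probability`, in input candidate order.
#' @export
dp4_style_probability <- function(deltas_by_candidate, params) {
  if (missing(params) || is.null(params) || !inherits(params, "probability_params")) {
    abort(paste("supply `params` via probability_params() with published",
                "error-distribution parameters (e.g. Goodman's DP4 or Sarotti's DP4+ values)"))
  }
  if (is.data.frame(deltas_by_candidate)) {
    stopifnot(all(c("candidate", "delta") %in% names(deltas_by_candidate)))
    deltas_by_candidate <- split(deltas_by_candidate,
                                 factor(deltas_by_candidate$candidate,
                                        levels = unique(deltas_by_candidate$candidate)))
  }
  if (length(deltas_by_candidate) < 2L) abort("need at least 2 candidates")
  if (is.null(names(deltas_by_candidate)) || any(names(deltas_by_candidate) == "")) {
    names(deltas_by_candidate) <- paste0("candidate_", seq_along(deltas_by_candidate))
  }
  loglik <- vapply(deltas_by_candidate, function(d) {
    z <- (d$delta - params$location) / params$scale
    sum(stats::dt(z, df = params$degrees_of_freedom, log = TRUE) - log(params$scale))
  }, numeric(1))
  w <- exp(unname(loglik) - max(loglik))
  tibble(candidate = names(deltas_by_candidate), probability = w / sum(w))
}
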