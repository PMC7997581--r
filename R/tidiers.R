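#' Tidy an alignment ranking
#'
#' @param x An `alignment_ranking` from [rank_alignments()].
#' @param ... Unused.
#' @return A tibble with one row per scheme: `rank`, `alignment`
#'   (experimental ids in calculated order), `mae_dddelta`, optional
#'   `avg_mae`, `n_terms`, `tie`.
#' @exportS3Method generics::tidy
tidy.alignment_ranking <- function(x, ...) {
  cols <- intersect(c("rank", "alignment", "mae_dddelta", "avg_mae",
                      "n_terms", "tie"), names(x$scores))
  x$scores[, cols]
}

#' One-row summary of an alignment ranking
#'
#' @inheritParams tidy.alignment_ranking
#' @return A one-row tibble: `n_sets`, `n_atoms`, `n_alignments`,
#'   `best_alignment`, `best_mae_dddelta` (ppm), `gap_to_second` (ppm),
#'   `n_tied`.
#' @exportS3Method generics::glance
glance.alignment_ranking <- function(x, ...) {
  tibble(n_sets = x$n,
         n_atoms = length(x$labels),
         n_alignments = nrow(x$scores),
         best_alignment = x$best_alignment,
         best_mae_dddelta = x$scores$mae_dddelta[1],
         gap_to_second = x$gap,
         n_tied = length(x$ties))
}

#' Tidy a classic per-set ranking
#'
#' @param x A `classic_ranking` from [classic_ranking()].
#' @param ... Unused.
#' @return The score tibble: one row per (experimental, calculated) pair
#'   with `score`, `best`, `tie`.
#' @exportS3Method generics::tidy
tidy.classic_ranking <- function(x, ...) x$scores

#' One-row summary of a classic per-set ranking
#'
#' @inheritParams tidy.classic_ranking
#' @return A one-row tibble: `metric`, `n_sets`, `n_atoms`,
#'   `n_ambiguous_calc` (calculated sets flagged best for more than one
#'   experimental set), `n_ties`.
#' @exportS3Method generics::glance
glance.classic_ranking <- function(x, ...) {
  best <- x$scores[x$scores$best, ]
  dup <- best %>% group_by(.data$calc_id) %>%
    summarise(k = dplyr::n_distinct(.data$exp_id)) %>% filter(.data$k > 1L)
  tibble(metric = x$metric,
         n_sets = length(x$exp_ids),
         n_atoms = length(x$labels),
         n_ambiguous_calc = nrow(dup),
         n_ties = sum(x$scores$tie & x$scores$best))
}
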