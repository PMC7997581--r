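#' Write an alignment ranking report
#'
#' Serialises an [rank_alignments()] result as JSON -- one entry per scheme
#' carrying its rank, the permutation (experimental set ids in calculated
#' order), `mae_dddelta` and, when computed, `avg_mae` -- plus run metadata
#' (set count, atom count, a hash of the ranking configuration). A
#' human-readable TSV mirror of the ranking table is written next to it.
#'
#' @param ranking An `alignment_ranking` object.
#' @param path Output path for the JSON report; the TSV mirror replaces the
#'   extension with `.tsv`.
#' @return Invisibly, a list with the `json` and `tsv` paths.
#' @export
write_report <- function(ranking, path) {
  stopifnot(inherits(ranking, "alignment_ranking"))
  if (nrow(ranking$scores) == 0L) abort("empty ranking")
  sc <- ranking$scores
  entries <- lapply(seq_len(nrow(sc)), function(i) {
    e <- list(rank = sc$rank[i],
              alignment = strsplit(sc$alignment[i], " ", fixed = TRUE)[[1]],
              mae_dddelta = sc$mae_dddelta[i],
              n_terms = sc$n_terms[i],
              tie = sc$tie[i])
    if ("avg_mae" %in% names(sc)) e$avg_mae <- sc$avg_mae[i]
    e
  })
  config <- list(n = ranking$n, metrics = ranking$metrics,
                 tie_tol = ranking$tie_tol,
                 calc_ids = ranking$calc_ids, exp_ids = ranking$exp_ids)
  report <- list(
    metadata = list(n_sets = ranking$n,
                    n_atoms = length(ranking$labels),
                    n_alignments = nrow(sc),
                    calc_sequence = ranking$calc_ids,
                    best_alignment = strsplit(ranking$best_alignment, " ",
                                              fixed = TRUE)[[1]],
                    gap_to_second = ranking$gap,
                    n_tied = length(ranking$ties),
                    config_hash = config_hash(config)),
    alignments = entries
  )
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  tsv_path <- sub("\\.[A-Za-z0-9]+$", ".tsv", path)
  if (identical(tsv_path, path)) tsv_path <- paste0(path, ".tsv")
  readr::write_tsv(sc[, setdiff(names(sc), "scheme")], tsv_path)
  invisible(list(json = path, tsv = tsv_path))
}

# md5 of the canonical JSON form of the configuration
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Read an alignment report back
#'
#' @param path Path to a JSON report written by [write_report()].
#' @return The parsed report list (`metadata`, `alignments`), alignment
#'   order preserved.
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = FALSE)
}
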