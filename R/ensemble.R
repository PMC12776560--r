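#' Configuration of the weighted greedy ensemble selector
#'
#' Defaults follow the reliability weighting used for the three-model
#' candidate pool: Protenix-derived candidates weighted 0.75, template-based
#' models 0.15, Boltz 0.10; selection anchored on Protenix conformation 2
#' and TBM conformation 1; five conformations selected in total (anchors
#' count toward the five). The diversity reward and prior-distance penalty
#' weights are exposed (default 1.0 each).
#'
#' @param model_weights Named numeric: reliability weight per source.
#' @param w_div Weight of the diversity reward (>= 0).
#' @param w_dist Weight of the distance-to-priors penalty (>= 0).
#' @param anchors Data frame with columns `source`, `index`: candidates
#'   seeding the selection, in order.
#' @param k Total number of conformations to select.
#' @return A list of class `ensemble_config`.
#' @export
ensemble_config <- function(model_weights = c(protenix = 0.75, tbm = 0.15,
                                              boltz = 0.10),
                            w_div = 1.0, w_dist = 1.0,
                            anchors = tibble(source = c("protenix", "tbm"),
                                             index = c(2L, 1L)),
                            k = 5L) {
  if (is.null(names(model_weights)) || any(!is.finite(model_weights))) {
    abort_input("model_weights must be a named finite numeric vector")
  }
  if (w_div < 0 || w_dist < 0) abort_input("w_div and w_dist must be >= 0")
  structure(list(model_weights = model_weights, w_div = w_div,
                 w_dist = w_dist, anchors = as_tibble(anchors),
                 k = as.integer(k)),
            class = "ensemble_config")
}

#' Candidate pool as a tibble
#'
#' @param source Character: generating model of each candidate (e.g.
#'   `"protenix"`, `"tbm"`, `"boltz"`).
#' @param index Integer: conformation index within its source (1..5).
#' @param chain List of [coord_chain()]s, all sharing length and sequence.
#' @return A tibble with columns `source`, `index`, `chain` (list-column).
#' @export
candidate_pool <- function(source, index, chain) {
  lens <- vapply(chain, chain_length, integer(1))
  if (length(unique(lens)) != 1) {
    abort_input("all candidates must share the residue count")
  }
  tibble(source = as.character(source), index = as.integer(index),
         chain = chain)
}

#' Kabsch-aligned C1' RMSD between two candidates
#'
#' @param a,b [coord_chain()]s (same-rank pairing).
#' @return RMSD in Angstroms.
#' @export
pairwise_rmsd <- function(a, b) rmsd_c1(a, b)

#' Mean pairwise RMSD of a candidate to the current selection
#'
#' @param candidate A [coord_chain()].
#' @param selected Non-empty list of [coord_chain()]s.
#' @return Mean of the pairwise Kabsch-aligned RMSDs, Angstroms.
#' @export
diversity <- function(candidate, selected) {
  if (length(selected) == 0) abort_input("`selected` must be non-empty")
  mean(vapply(selected, function(s) pairwise_rmsd(candidate, s), numeric(1)))
}

#' Mean RMSD of a candidate to the anchor conformations
#'
#' @param candidate A [coord_chain()].
#' @param anchors Non-empty list of [coord_chain()]s (the priors).
#' @return Mean anchor RMSD, Angstroms.
#' @export
distance_to_priors <- function(candidate, anchors) {
  if (length(anchors) == 0) abort_input("`anchors` must be non-empty")
  mean(vapply(anchors, function(s) pairwise_rmsd(candidate, s), numeric(1)))
}

#' Greedy selection score of a candidate
#'
#' `w_model(source) * (w_div * diversity - w_dist * distance_to_priors)`:
#' reliability-weighted balance of structural diversity against drift from
#' the anchor conformations.
#'
#' @param candidate A [coord_chain()].
#' @param source Source tag of the candidate (must have a model weight).
#' @param selected List of already-selected [coord_chain()]s.
#' @param anchors List of anchor [coord_chain()]s.
#' @param config An [ensemble_config()].
#' @return A one-row tibble: `score`, `diversity`, `distance_to_priors`.
#' @export
candidate_score <- function(candidate, source, selected, anchors, config) {
  if (!source %in% names(config$model_weights)) {
    abort_input(paste0("no model weight for source '", source, "'"))
  }
  div <- diversity(candidate, selected)
  dst <- distance_to_priors(candidate, anchors)
  tibble(score = unname(config$model_weights[source]) *
           (config$w_div * div - config$w_dist * dst),
         diversity = div, distance_to_priors = dst)
}

#' Greedy diversity-aware ensemble selection
#'
#' Selects `k` conformations from a candidate pool. The selection is
#' initialized with the anchors (in configuration order); each following
#' step scores every unselected candidate against the *current* selection
#' with [candidate_score()] and adds the arg-max. Ties are broken by
#' source order (`protenix < tbm < boltz`, i.e. the order of
#' `model_weights`), then by conformation index, making runs reproducible.
#'
#' @param candidates A [candidate_pool()] tibble.
#' @param config An [ensemble_config()].
#' @return The selection trace: a tibble with one row per selected
#'   conformation, columns `step`, `source`, `index`, `anchor`, `score`,
#'   `diversity`, `distance_to_priors`, and the selected `chain`
#'   list-column. Anchor rows carry `NA` scores.
#' @export
select_ensemble <- function(candidates, config = ensemble_config()) {
  if (!all(c("source", "index", "chain") %in% names(candidates))) {
    abort_input("candidates must be a candidate_pool() tibble")
  }
  k <- config$k
  if (k > nrow(candidates)) abort_input("k exceeds the number of candidates")
  src_order <- match(candidates$source, names(config$model_weights))
  if (anyNA(src_order)) {
    abort_input("candidate source without a model weight")
  }
  sel <- integer(0)
  rows <- list()
  anchor_idx <- integer(0)
  for (i in seq_len(nrow(config$anchors))) {
    hit <- which(candidates$source == config$anchors$source[i] &
                   candidates$index == config$anchors$index[i])
    if (length(hit) != 1) {
      abort_input(sprintf("anchor %s_%d missing from the candidate pool",
                          config$anchors$source[i], config$anchors$index[i]))
    }
    anchor_idx <- c(anchor_idx, hit)
  }
  anchors <- candidates$chain[anchor_idx]
  for (i in seq_along(anchor_idx)) {
    if (length(sel) >= k) break
    sel <- c(sel, anchor_idx[i])
    rows[[length(rows) + 1]] <- tibble(
      step = length(sel), source = candidates$source[anchor_idx[i]],
      index = candidates$index[anchor_idx[i]], anchor = TRUE,
      score = NA_real_, diversity = NA_real_, distance_to_priors = NA_real_)
  }
  while (length(sel) < k) {
    remaining <- setdiff(seq_len(nrow(candidates)), sel)
    scored <- purrr::map_dfr(remaining, function(j) {
      candidate_score(candidates$chain[[j]], candidates$source[j],
                      candidates$chain[sel], anchors, config)
    })
    ord <- order(-scored$score, src_order[remaining],
                 candidates$index[remaining])
    best <- remaining[ord[1]]
    sel <- c(sel, best)
    rows[[length(rows) + 1]] <- tibble(
      step = length(sel), source = candidates$source[best],
      index = candidates$index[best], anchor = FALSE,
      score = scored$score[ord[1]], diversity = scored$diversity[ord[1]],
      distance_to_priors = scored$distance_to_priors[ord[1]])
  }
  out <- dplyr::bind_rows(rows)
  out$chain <- candidates$chain[sel]
  out
}
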