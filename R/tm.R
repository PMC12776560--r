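#' Length-dependent TM-score distance scale d0 for RNA
#'
#' The distance scaling factor that makes TM-scores comparable across
#' chain lengths: `0.6 * sqrt(Lref - 0.5) - 2.5` for `Lref >= 30`, and the
#' fixed values 0.3, 0.4, 0.5, 0.6, 0.7 Angstroms for `Lref` below 12,
#' 12-15, 16-19, 20-23 and 24-29 respectively. With this calibration a
#' TM-score above 0.45 indicates a shared global fold irrespective of
#' length.
#'
#' @param lref Number of solved residues in the reference structure
#'   (positive integers; vectorized).
#' @return d0 in Angstroms.
#' @examples
#' d0_of(c(10, 13, 30))
#' @export
d0_of <- function(lref) {
  lref <- as.numeric(lref)
  if (any(is.na(lref)) || any(lref < 1) || any(lref != floor(lref))) {
    abort_input("`lref` must be positive integers")
  }
  ifelse(lref >= 30, 0.6 * sqrt(lref - 0.5) - 2.5,
         ifelse(lref >= 24, 0.7,
                ifelse(lref >= 20, 0.6,
                       ifelse(lref >= 16, 0.5,
                              ifelse(lref >= 12, 0.4, 0.3)))))
}

#' Fold-correctness threshold
#'
#' Classify TM values as correct global folds: scores above 0.45
#' correspond to a shared global fold for RNA.
#'
#' @param tm TM value(s).
#' @param threshold Fold threshold (default 0.45).
#' @return Logical vector.
#' @export
is_correct_fold <- function(tm, threshold = 0.45) tm > threshold

#' TM-score for a fixed pairing and fixed superposition
#'
#' The raw TM sum `(1/Lref) * sum( 1 / (1 + (d_i/d0)^2) )` with distances
#' measured after applying `transform` to the model — no optimization of
#' any kind. `Lref` is the solved length of the reference.
#'
#' @param model,reference [coord_chain()]s.
#' @param alignment A data frame with columns `model_pos` and `ref_pos`
#'   (1-based residue positions, both strictly increasing), as in
#'   [tm_alignment()].
#' @param transform A [rigid_transform()] (or `superposition`) applied to
#'   the model; identity by default.
#' @param lref,d0 Optional overrides; by default `Lref` is
#'   `solved_length(reference)` and `d0 = d0_of(lref)`.
#' @return The TM value.
#' @export
tm_fixed <- function(model, reference, alignment,
                     transform = rigid_transform(),
                     lref = solved_length(reference), d0 = d0_of(lref)) {
  check_alignment(alignment, chain_length(model), chain_length(reference))
  A <- coords_at(model, alignment$model_pos, "model")
  B <- coords_at(reference, alignment$ref_pos, "reference")
  At <- sweep(A %*% t(transform$rotation), 2, transform$translation, "+")
  di <- sqrt(rowSums((At - B)^2))
  sum(1 / (1 + (di / d0)^2)) / lref
}

#' Construct an alignment map
#'
#' @param model_pos,ref_pos Strictly increasing 1-based residue positions
#'   of equal length.
#' @return A tibble with columns `model_pos`, `ref_pos`.
#' @export
tm_alignment <- function(model_pos, ref_pos) {
  al <- tibble(model_pos = as.integer(model_pos), ref_pos = as.integer(ref_pos))
  if (nrow(al) > 1 &&
      (any(diff(al$model_pos) <= 0) || any(diff(al$ref_pos) <= 0))) {
    abort_input("alignment indices must be strictly increasing on both sides")
  }
  al
}

check_alignment <- function(alignment, n_model, n_ref) {
  if (!all(c("model_pos", "ref_pos") %in% names(alignment))) {
    abort_input("alignment needs `model_pos` and `ref_pos` columns")
  }
  mp <- alignment$model_pos
  rp <- alignment$ref_pos
  if (length(mp) != length(rp)) abort_input("alignment sides differ in length")
  if (length(mp) > 1 && (any(diff(mp) <= 0) || any(diff(rp) <= 0))) {
    abort_input("alignment indices must be strictly increasing on both sides")
  }
  if (any(mp < 1 | mp > n_model) || any(rp < 1 | rp > n_ref)) {
    abort_input("alignment index out of range")
  }
  invisible(alignment)
}

#' Maximize TM-score over superpositions for a fixed pairing
#'
#' Computes `max` over rigid superpositions of the TM sum for a given
#' residue pairing. Small pairings (up to 10 pairs) are solved exactly over
#' Kabsch fits of every subset of three or more pairs; larger pairings use
#' fragment-seeded iterative refinement (seeds from contiguous aligned
#' fragments, distance-cutoff reselection starting at `d0 + 1.5` Angstroms
#' shrinking by 0.5 on stagnation with a 0.5 floor, at most 30 iterations
#' per seed). TM is always evaluated over all pairs of the pairing.
#'
#' @inheritParams tm_fixed
#' @return A `tm_result` with `mode = "fixed"`.
#' @export
optimize_superposition <- function(model, reference, alignment,
                                   lref = solved_length(reference),
                                   d0 = d0_of(lref)) {
  check_alignment(alignment, chain_length(model), chain_length(reference))
  if (nrow(alignment) < 3) abort_input("need at least 3 aligned pairs")
  A <- coords_at(model, alignment$model_pos, "model")
  B <- coords_at(reference, alignment$ref_pos, "reference")
  fit <- cpp_optimize_superposition(A, B, lref, d0)
  new_tm_result(fit$tm, "fixed", alignment, fit$rotation,
                as.numeric(fit$translation), lref, d0, A, B)
}

#' Sequence-dependent TM-score
#'
#' TM-score with the residue correspondence forced by sequence rank: model
#' position i pairs with reference position i, restricted to positions
#' solved in both structures. The superposition is optimized as in
#' [optimize_superposition()]; `Lref` is the solved length of the
#' reference.
#'
#' @param model,reference [coord_chain()]s representing the same sequence
#'   (equal residue counts).
#' @return A `tm_result` with `mode = "tm_score"`.
#' @export
tm_score <- function(model, reference) {
  if (chain_length(model) != chain_length(reference)) {
    abort_input("tm_score needs model and reference of equal residue count")
  }
  pr <- common_solved(model, reference)
  if (length(pr$pos) < 3) {
    abort_unscorable("fewer than 3 positions solved in both structures")
  }
  al <- tm_alignment(pr$pos, pr$pos)
  out <- optimize_superposition(model, reference, al)
  out$mode <- "tm_score"
  out
}

#' Sequence-independent TM-align
#'
#' Jointly optimizes the residue alignment and the superposition,
#' ignoring nucleotide identity and residue numbering entirely (only chain
#' order matters). Starting alignments are gapless threadings at every
#' offset (plus, for chains of up to 10 solved residues each, every
#' monotone 3-pair seed, which lets the search reach optima governed by a
#' few well-matching residues); each round alternates superposition
#' optimization with a global dynamic-programming realignment (gap-open
#' -0.6, gap-extension 0) until the alignment repeats, up to 20 rounds per
#' start. The score is normalized by the reference: `tm_align(a, b)` is
#' generally different from `tm_align(b, a)`.
#'
#' @param model,reference [coord_chain()]s with at least 3 solved residues
#'   each.
#' @param gap_open Gap-open penalty of the realignment DP.
#' @return A `tm_result` with `mode = "tm_align"`.
#' @export
tm_align <- function(model, reference, gap_open = -0.6) {
  sm <- solved_coords(model)
  sr <- solved_coords(reference)
  if (nrow(sm$xyz) < 3 || nrow(sr$xyz) < 3) {
    abort_unscorable("both structures need at least 3 solved residues")
  }
  lref <- solved_length(reference)
  d0 <- d0_of(lref)
  fit <- cpp_tm_align(sm$xyz, sr$xyz, lref, d0, gap_open)
  al <- tm_alignment(sm$pos[fit$pairs[, 1] + 1L], sr$pos[fit$pairs[, 2] + 1L])
  A <- coords_at(model, al$model_pos)
  B <- coords_at(reference, al$ref_pos)
  new_tm_result(fit$tm, "tm_align", al, fit$rotation,
                as.numeric(fit$translation), lref, d0, A, B)
}

#' C1' RMSD between two structures
#'
#' Kabsch RMSD over the same-rank pairing restricted to positions solved
#' in both structures.
#'
#' @param model,reference [coord_chain()]s.
#' @return RMSD in Angstroms.
#' @export
rmsd_c1 <- function(model, reference) {
  pr <- common_solved(model, reference)
  if (length(pr$pos) < 1) abort_unscorable("no positions solved in both structures")
  cpp_kabsch(pr$a, pr$b)$rmsd
}

new_tm_result <- function(tm, mode, alignment, rotation, translation,
                          lref, d0, A, B) {
  At <- sweep(A %*% t(rotation), 2, translation, "+")
  di <- sqrt(rowSums((At - B)^2))
  structure(list(tm = tm, mode = mode, lref = lref,
                 lalign = nrow(alignment), d0 = d0,
                 alignment = alignment,
                 superposition = structure(
                   list(rotation = rotation, translation = translation,
                        distances = di, rmsd = sqrt(mean(di^2))),
                   class = "superposition")),
            class = "tm_result")
}

#' @export
print.tm_result <- function(x, ...) {
  cat(sprintf("<tm_result %s: tm = %.4f (Lref = %d, Lalign = %d, d0 = %.3f A)>\n",
              x$mode, x$tm, x$lref, x$lalign, x$d0))
  invisible(x)
}

#' Per-pair detail of a TM result
#'
#' @param x A `tm_result`.
#' @param ... Unused.
#' @return One row per aligned pair: residue positions, post-superposition
#'   distance and the pair's TM contribution.
#' @export
tidy.tm_result <- function(x, ...) {
  d <- x$superposition$distances
  tibble(model_pos = x$alignment$model_pos,
         ref_pos = x$alignment$ref_pos,
         distance = d,
         contribution = 1 / (1 + (d / x$d0)^2) / x$lref)
}

#' One-row summary of a TM result
#'
#' @inheritParams tidy.tm_result
#' @export
glance.tm_result <- function(x, ...) {
  tibble(tm = x$tm, mode = x$mode, lref = x$lref, lalign = x$lalign,
         d0 = x$d0, aligned_rmsd = x$superposition$rmsd,
         correct_fold = is_correct_fold(x$tm))
}
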