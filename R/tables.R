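#' Read a target-metadata CSV
#'
#' The targets file lists one RNA per row with at least `target_id` and
#' `sequence` columns; `description` and `temporal_cutoff` are carried
#' through when present. Sequences are uppercased and any `T` is replaced
#' with `U` (DNA-formatted inputs are common upstream of RNA pipelines).
#'
#' @param file Path to the CSV (or literal CSV text).
#' @return A tibble with columns `target_id`, `sequence`, `description`,
#'   `temporal_cutoff`.
#' @export
read_targets_csv <- function(file) {
  df <- read_csv_input(file)
  need <- c("target_id", "sequence")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    abort_input(paste0("targets CSV is missing column(s): ",
                       paste(miss, collapse = ", ")))
  }
  seq <- gsub("T", "U", toupper(as.character(df$sequence)))
  if (any(is.na(seq) | seq == "")) abort_input("empty sequence field in targets CSV")
  bad <- grepl("[^ACGUN]", seq)
  if (any(bad)) {
    abort_input(paste0("sequence for target ", df$target_id[bad][1],
                       " contains characters outside A/C/G/U/N"))
  }
  tibble(target_id = as.character(df$target_id),
         sequence = seq,
         description = if ("description" %in% names(df))
           as.character(df$description) else NA_character_,
         temporal_cutoff = if ("temporal_cutoff" %in% names(df))
           as.character(df$temporal_cutoff) else NA_character_)
}

#' Read a five-model submission CSV
#'
#' Submissions are wide tables with one row per residue of the target
#' sequence, in order: columns `ID` (`<target_id>_<resid>`), `resname`,
#' `resid`, then `x_1,y_1,z_1, ..., x_5,z_5,y_5` for the five predicted
#' coordinate sets. Missing coordinate cells mean "unsolved in that model".
#'
#' @param file Path to the CSV (or literal CSV text).
#' @param target A one-row target record (as from [read_targets_csv()]), or
#'   a list with `target_id` and `sequence`.
#' @return A `submission_set`: list with `target_id` and `models`, a list
#'   of five [coord_chain()]s (possibly fewer, flagged via the
#'   `complete` field).
#' @export
read_submission_csv <- function(file, target) {
  read_model_table(file, target, n_models = 5L, kind = "submission")
}

#' Read a solution CSV with one or more ground-truth conformations
#'
#' Same schema as the submission file, but with one coordinate triple per
#' alternative ground-truth conformation (`x_1..z_k` for k conformations).
#'
#' @inheritParams read_submission_csv
#' @return A `solution_set`: list with `target_id` and `conformations`.
#' @export
read_solution_csv <- function(file, target) {
  out <- read_model_table(file, target, n_models = NULL, kind = "solution")
  structure(list(target_id = out$target_id, conformations = out$models),
            class = "solution_set")
}

read_model_table <- function(file, target, n_models, kind) {
  df <- read_csv_input(file)
  need <- c("ID", "resname", "resid")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    abort_input(paste0(kind, " CSV is missing column(s): ",
                       paste(miss, collapse = ", ")))
  }
  target_id <- as.character(target$target_id)
  sequence <- strsplit(as.character(target$sequence), "")[[1]]
  if (nrow(df) != length(sequence)) {
    abort_input(sprintf("%s CSV for %s has %d rows but the sequence has %d residues",
                        kind, target_id, nrow(df), length(sequence)))
  }
  mism <- which(toupper(as.character(df$resname)) != sequence)
  if (length(mism) > 0) {
    abort_input(sprintf("resname mismatch at position %d of %s (%s vs %s)",
                        mism[1], target_id, df$resname[mism[1]], sequence[mism[1]]))
  }
  want_id <- paste0(target_id, "_", df$resid)
  if (any(as.character(df$ID) != want_id)) {
    abort_input(paste0("ID column does not follow <target_id>_<resid> for ", target_id))
  }
  ks <- sort(as.integer(sub("^x_", "", grep("^x_[0-9]+$", names(df), value = TRUE))))
  if (!is.null(n_models)) {
    if (!all(seq_len(n_models) %in% ks)) ks <- ks  # fewer models: flagged below
    ks <- ks[ks <= n_models]
  }
  if (length(ks) == 0) abort_input(paste0("no coordinate columns (x_1..) in ", kind, " CSV"))
  models <- lapply(ks, function(k) {
    xyz <- lapply(c("x", "y", "z"), function(ax) {
      col <- paste0(ax, "_", k)
      if (!col %in% names(df)) abort_input(paste0("missing column ", col))
      v <- df[[col]]
      chr <- as.character(v)
      num <- suppressWarnings(as.numeric(chr))
      bad <- !is.na(chr) & chr != "" & is.na(num)
      if (any(bad)) {
        abort_input(sprintf("non-numeric coordinate '%s' in column %s", chr[bad][1], col))
      }
      num
    })
    # a residue is unsolved only if all three coordinates are missing
    partial <- rowSums(is.na(cbind(xyz[[1]], xyz[[2]], xyz[[3]]))) %in% 1:2
    if (any(partial)) {
      abort_input(sprintf("residue %s has a partial coordinate triple in model %d",
                          df$resid[partial][1], k))
    }
    coord_chain(seq_id = as.integer(df$resid), code = sequence,
                x = xyz[[1]], y = xyz[[2]], z = xyz[[3]], chain_id = "A")
  })
  structure(list(target_id = target_id, models = models,
                 complete = is.null(n_models) || length(models) == n_models),
            class = "submission_set")
}

#' Bundle predicted models for one target
#'
#' @param target_id Target identifier.
#' @param models List of [coord_chain()]s (five for a complete submission).
#' @export
submission_set <- function(target_id, models) {
  stopifnot(length(models) >= 1)
  structure(list(target_id = as.character(target_id), models = models,
                 complete = length(models) == 5L),
            class = "submission_set")
}

#' Bundle ground-truth conformations for one target
#'
#' @param target_id Target identifier.
#' @param conformations List of [coord_chain()]s, one per alternative
#'   ground-truth conformation (at least one).
#' @export
solution_set <- function(target_id, conformations) {
  stopifnot(length(conformations) >= 1)
  lens <- vapply(conformations, chain_length, integer(1))
  if (length(unique(lens)) != 1) {
    abort_input("all solution conformations must share the sequence length")
  }
  if (any(vapply(conformations, solved_length, integer(1)) == 0)) {
    abort_input("each solution conformation needs at least one solved residue")
  }
  structure(list(target_id = as.character(target_id),
                 conformations = conformations),
            class = "solution_set")
}

read_csv_input <- function(file) {
  if (length(file) == 1 && !grepl("\n", file, fixed = TRUE) && !file.exists(file)) {
    abort_input(paste0("file not found: ", file))
  }
  readr::read_csv(if (grepl("\n", file[1], fixed = TRUE)) I(file) else file,
                  show_col_types = FALSE, progress = FALSE)
}

#' Write a submission or solution CSV
#'
#' Inverse of [read_submission_csv()] / [read_solution_csv()]: writes the
#' wide per-residue table for a list of coordinate sets of one target.
#'
#' @param models List of [coord_chain()]s sharing one sequence.
#' @param target_id Target identifier used in the `ID` column.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_model_csv <- function(models, target_id, path) {
  base <- models[[1]]
  df <- tibble(ID = paste0(target_id, "_", base$seq_id),
               resname = base$code, resid = base$seq_id)
  for (k in seq_along(models)) {
    df[[paste0("x_", k)]] <- models[[k]]$x
    df[[paste0("y_", k)]] <- models[[k]]$y
    df[[paste0("z_", k)]] <- models[[k]]$z
  }
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}
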