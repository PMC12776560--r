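#' Build a C1' coordinate chain
#'
#' The central container of the package: one row per nucleotide, holding the
#' residue number, the one-letter code and the coordinate of its C1' atom in
#' Angstroms. A residue whose structure was not solved keeps `NA`
#' coordinates; such residues count towards [chain_length()] but not
#' [solved_length()]. Row order is the order of appearance in the source
#' (file order), which is the order all scoring operations use.
#'
#' @param seq_id Integer residue numbers. Gaps are allowed (crystal
#'   structures skip numbers); a non-increasing sequence triggers a warning
#'   but file order is kept.
#' @param code One-letter nucleotide codes, uppercase, from `A C G U N`.
#' @param x,y,z Coordinates in Angstroms; `NA` (in all three) marks an
#'   unsolved residue.
#' @param chain_id Short chain identifier.
#' @param ins Insertion codes, appended to the residue identity (default
#'   none).
#' @return A tibble of class `coord_chain` with columns `seq_id`, `ins`,
#'   `code`, `x`, `y`, `z` and a `chain_id` attribute.
#' @examples
#' ch <- coord_chain(1:3, c("A", "C", "G"),
#'                   x = c(0, 5.9, 11.8), y = c(0, 0, 0), z = c(0, 0, 0))
#' chain_length(ch)
#' solved_length(ch)
#' @export
coord_chain <- function(seq_id, code, x, y, z, chain_id = "A", ins = "") {
  n <- length(seq_id)
  if (n == 0) abort_input("a coord_chain needs at least one residue")
  code <- toupper(as.character(code))
  bad <- !code %in% c("A", "C", "G", "U", "N")
  if (any(bad)) {
    abort_input(paste0("invalid nucleotide code(s): ",
                       paste(unique(code[bad]), collapse = ", ")))
  }
  ins <- rep_len(as.character(ins), n)
  x <- as.double(x); y <- as.double(y); z <- as.double(z)
  if (length(x) != n || length(y) != n || length(z) != n) {
    abort_input("coordinate vectors must match the number of residues")
  }
  solved <- !is.na(x)
  if (any(is.na(y) != is.na(x)) || any(is.na(z) != is.na(x))) {
    abort_input("a residue must have either all three coordinates or none")
  }
  if (any(!is.finite(c(x[solved], y[solved], z[solved])))) {
    abort_input("coordinates must be finite")
  }
  seq_id <- as.integer(seq_id)
  if (n > 1 && any(diff(seq_id) <= 0)) {
    warn("seq_id not strictly increasing; keeping file order")
  }
  out <- tibble(seq_id = seq_id, ins = ins, code = code, x = x, y = y, z = z)
  attr(out, "chain_id") <- as.character(chain_id)
  class(out) <- c("coord_chain", class(out))
  out
}

#' @rdname coord_chain
#' @param chain A `coord_chain`.
#' @export
chain_length <- function(chain) nrow(chain)

#' @rdname coord_chain
#' @export
solved_length <- function(chain) sum(!is.na(chain$x))

#' @rdname coord_chain
#' @export
chain_id <- function(chain) attr(chain, "chain_id")

#' @rdname coord_chain
#' @export
chain_sequence <- function(chain) paste(chain$code, collapse = "")

# Solved coordinates as a k x 3 matrix plus the 1-based residue positions
# they came from.
solved_coords <- function(chain) {
  keep <- which(!is.na(chain$x))
  list(xyz = cbind(chain$x[keep], chain$y[keep], chain$z[keep]),
       pos = keep)
}

# Coordinate matrix for explicit residue positions; errors if any is
# unsolved.
coords_at <- function(chain, pos, what = "residue") {
  if (any(pos < 1 | pos > nrow(chain))) {
    abort_input(paste(what, "position out of range"))
  }
  if (anyNA(chain$x[pos])) {
    abort_unscorable(paste("aligned", what, "position(s) unsolved"))
  }
  cbind(chain$x[pos], chain$y[pos], chain$z[pos])
}

#' @export
print.coord_chain <- function(x, ...) {
  cat(sprintf("<coord_chain %s: %d residues, %d solved>\n",
              chain_id(x), chain_length(x), solved_length(x)))
  NextMethod()
}
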