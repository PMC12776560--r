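#' Kabsch superposition of paired point sets
#'
#' Least-squares rigid superposition: finds the proper rotation and
#' translation mapping point set `a` onto point set `b` (SVD solution with
#' determinant sign correction, so reflections are never returned), and the
#' per-pair distances and RMSD after superposition.
#'
#' @param a,b Either k x 3 coordinate matrices with matching rows, or two
#'   [coord_chain()]s, in which case the same-rank pairing over positions
#'   solved in both chains is used.
#' @return A `superposition` object: list with `rotation` (3 x 3),
#'   `translation` (length 3), `distances` (per pair, Angstroms) and
#'   `rmsd`. The transform maps `a` coordinates into `b`'s frame:
#'   `x' = R x + t`.
#' @examples
#' a <- matrix(rnorm(12), 4, 3)
#' kabsch(a, a)$rmsd
#' @export
kabsch <- function(a, b) {
  if (inherits(a, "coord_chain") && inherits(b, "coord_chain")) {
    pr <- common_solved(a, b)
    a <- pr$a
    b <- pr$b
  }
  a <- as_xyz(a)
  b <- as_xyz(b)
  if (nrow(a) != nrow(b)) abort_input("point sets must have equal length")
  if (nrow(a) < 1) abort_input("need at least one pair of points")
  fit <- cpp_kabsch(a, b)
  structure(list(rotation = fit$rotation,
                 translation = as.numeric(fit$translation),
                 distances = as.numeric(fit$distances),
                 rmsd = fit$rmsd),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition: %d pairs, rmsd %.4f A>\n",
              length(x$distances), x$rmsd))
  invisible(x)
}

#' @export
tidy.superposition <- function(x, ...) {
  tibble(pair = seq_along(x$distances), distance = x$distances)
}

#' @export
glance.superposition <- function(x, ...) {
  tibble(n_pairs = length(x$distances), rmsd = x$rmsd)
}

#' Build or apply a rigid transform
#'
#' @param rotation 3 x 3 proper rotation matrix.
#' @param translation Length-3 translation, Angstroms.
#' @return `rigid_transform()` returns a `rigid_transform` object;
#'   `apply_transform()` returns the transformed chain (codes, ids and
#'   unsolved residues untouched).
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  if (!all(dim(rotation) == c(3, 3)) || length(translation) != 3) {
    abort_input("rotation must be 3 x 3 and translation length 3")
  }
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6 ||
      abs(det(rotation) - 1) > 1e-6) {
    abort_input("rotation must be proper orthogonal")
  }
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @rdname rigid_transform
#' @param transform A `rigid_transform` (or a `superposition`, whose
#'   transform component is used).
#' @param chain A [coord_chain()].
#' @export
apply_transform <- function(transform, chain) {
  R <- transform$rotation
  t <- transform$translation
  solved <- !is.na(chain$x)
  if (any(solved)) {
    xyz <- cbind(chain$x[solved], chain$y[solved], chain$z[solved])
    new <- xyz %*% t(R)
    new <- sweep(new, 2, t, "+")
    chain$x[solved] <- new[, 1]
    chain$y[solved] <- new[, 2]
    chain$z[solved] <- new[, 3]
  }
  chain
}

#' @rdname rigid_transform
#' @param first,second Transforms; `compose_transforms(first, second)`
#'   returns the transform equivalent to applying `first` then `second`.
#' @export
compose_transforms <- function(first, second) {
  rigid_transform(second$rotation %*% first$rotation,
                  as.numeric(second$rotation %*% first$translation) +
                    second$translation)
}

#' @rdname rigid_transform
#' @export
invert_transform <- function(transform) {
  Rt <- t(transform$rotation)
  rigid_transform(Rt, -as.numeric(Rt %*% transform$translation))
}

as_xyz <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) != 3) abort_input("coordinates must be a k x 3 matrix")
  storage.mode(m) <- "double"
  if (any(!is.finite(m))) abort_input("coordinates must be finite")
  m
}

# Same-rank pairing over positions solved in both chains.
common_solved <- function(a, b) {
  n <- min(chain_length(a), chain_length(b))
  keep <- which(!is.na(a$x[seq_len(n)]) & !is.na(b$x[seq_len(n)]))
  list(a = cbind(a$x[keep], a$y[keep], a$z[keep]),
       b = cbind(b$x[keep], b$y[keep], b$z[keep]),
       pos = keep)
}
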