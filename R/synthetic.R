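#' Generate a synthetic C1' chain
#'
#' Produces RNA-like coarse-grained chains for testing and simulation:
#' `"helix"` places points on a regular helix (rise 2.8 A, twist 32.7
#' degrees, radius 9.4 A — idealized A-form-like C1' geometry; these are
#' package constants chosen to give plausible inter-residue distances, not
#' measured values); `"coil"` is a self-avoiding random walk with step
#' length 5.9 +/- 0.5 A (approximately the C1'-C1' virtual bond) and a 3 A
#' clash distance; `"two_helix_bend"` joins two helices at `bend_angle`.
#' Gaussian noise of sd `noise_sigma` is added per coordinate. Chains are
#' pure functions of `seed`.
#'
#' @param n Number of residues (>= 3).
#' @param kind `"helix"`, `"coil"` or `"two_helix_bend"`.
#' @param noise_sigma Per-coordinate Gaussian noise, Angstroms (>= 0).
#' @param seed Integer seed (required; no global RNG state is touched).
#' @param bend_angle Bend between the two helix axes in degrees
#'   (`two_helix_bend` only; default 60).
#' @param chain_id Chain identifier of the result.
#' @return A [coord_chain()] with a random A/C/G/U sequence.
#' @examples
#' h <- generate_chain(30, "helix", seed = 1)
#' solved_length(h)
#' @export
generate_chain <- function(n, kind = c("helix", "coil", "two_helix_bend"),
                           noise_sigma = 0, seed, bend_angle = 60,
                           chain_id = "A") {
  kind <- match.arg(kind)
  n <- as.integer(n)
  if (n < 3) abort_input("`n` must be at least 3")
  if (noise_sigma < 0) abort_input("`noise_sigma` must be >= 0")
  with_seed(seed, {
    xyz <- switch(kind,
                  helix = helix_points(n),
                  coil = coil_points(n),
                  two_helix_bend = bent_helix_points(n, bend_angle))
    if (noise_sigma > 0) {
      xyz <- xyz + matrix(rnorm(3 * n, sd = noise_sigma), n, 3)
    }
    code <- sample(c("A", "C", "G", "U"), n, replace = TRUE)
    coord_chain(seq_id = seq_len(n), code = code,
                x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                chain_id = chain_id)
  })
}

helix_points <- function(n, rise = 2.8, twist = 32.7, radius = 9.4) {
  th <- (seq_len(n) - 1) * twist * pi / 180
  cbind(radius * cos(th), radius * sin(th), (seq_len(n) - 1) * rise)
}

coil_points <- function(n, step = 5.9, step_sd = 0.5, clash = 3.0) {
  pts <- matrix(0, n, 3)
  for (i in seq_len(n)[-1]) {
    for (attempt in seq_len(1000)) {
      dir <- rnorm(3)
      dir <- dir / sqrt(sum(dir^2))
      cand <- pts[i - 1, ] + dir * rnorm(1, step, step_sd)
      if (i == 2) break
      d2 <- rowSums(sweep(pts[seq_len(i - 2), , drop = FALSE], 2, cand)^2)
      if (min(d2) > clash^2) break
      if (attempt == 1000) abort("self-avoiding walk failed to extend")
    }
    pts[i, ] <- cand
  }
  pts
}

bent_helix_points <- function(n, bend_angle, rise = 2.8) {
  n1 <- n %/% 2
  n2 <- n - n1
  h1 <- helix_points(n1)
  h2 <- helix_points(n2)
  a <- bend_angle * pi / 180
  rot <- matrix(c(cos(a), 0, sin(a), 0, 1, 0, -sin(a), 0, cos(a)), 3, 3)
  h2 <- h2 %*% t(rot)
  axis <- as.numeric(rot %*% c(0, 0, 1))
  offset <- h1[n1, ] + axis * rise - h2[1, ]
  h2 <- sweep(h2, 2, offset, "+")
  rbind(h1, h2)
}

#' Perturb a chain with Gaussian coordinate noise
#'
#' Adds iid Gaussian noise (sd `sigma` per coordinate) to every solved
#' residue; ids, codes and unsolved residues are untouched. At large n the
#' Kabsch RMSD to the original approaches `sigma * sqrt(3)`.
#'
#' @param chain A [coord_chain()].
#' @param sigma Noise sd per coordinate, Angstroms.
#' @param seed Integer seed.
#' @return The perturbed chain.
#' @export
perturb_chain <- function(chain, sigma, seed) {
  if (sigma < 0) abort_input("`sigma` must be >= 0")
  if (sigma == 0) return(chain)
  with_seed(seed, {
    solved <- which(!is.na(chain$x))
    noise <- matrix(rnorm(3 * length(solved), sd = sigma), ncol = 3)
    chain$x[solved] <- chain$x[solved] + noise[, 1]
    chain$y[solved] <- chain$y[solved] + noise[, 2]
    chain$z[solved] <- chain$z[solved] + noise[, 3]
    chain
  })
}

#' Write a self-contained mini-competition fixture suite
#'
#' Builds a complete, deterministic evaluation scenario on disk: a targets
#' CSV with three targets (a 30-mer helix, a 40-mer bent two-helix chain
#' with *two* alternative ground-truth conformations, and a 25-mer coil);
#' solution CSVs; five-model submission CSVs for three groups spanning
#' near-native (sigma = 0.5 A), intermediate (sigma = 2 A) and decoy
#' (independent coils) accuracy; and a 15-candidate ensemble directory
#' (`<source>_<index>.pdb` for protenix/tbm/boltz). By construction the
#' near-native group ranks first by mean TM-align and the two-conformation
#' target exercises the max-over-solutions rule.
#'
#' @param out_dir Directory to create the suite in.
#' @param seed Integer seed; the suite is a pure function of it.
#' @return Invisibly, a list with the layout: `targets_csv`,
#'   `solutions_dir`, `submissions_dir`, `ensemble_dir`, `groups`,
#'   `targets` (the targets tibble).
#' @export
make_fixture_suite <- function(out_dir, seed) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sol_dir <- file.path(out_dir, "solutions")
  sub_dir <- file.path(out_dir, "submissions")
  ens_dir <- file.path(out_dir, "ensemble")
  for (d in c(sol_dir, sub_dir, ens_dir)) {
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
  }
  base_seed <- as.integer(seed) %% 100000L

  conf <- list(
    T1 = list(generate_chain(30, "helix", seed = base_seed + 1L)),
    T2 = list(generate_chain(40, "two_helix_bend", seed = base_seed + 2L,
                             bend_angle = 70),
              generate_chain(40, "two_helix_bend", seed = base_seed + 2L,
                             bend_angle = 110)),
    T3 = list(generate_chain(25, "coil", seed = base_seed + 3L)))

  targets <- tibble(
    target_id = names(conf),
    sequence = vapply(conf, function(cs) chain_sequence(cs[[1]]), character(1)),
    description = c("idealized helix", "bent two-helix chain, 2 conformations",
                    "self-avoiding coil"),
    temporal_cutoff = "2025-05-29")
  targets_csv <- file.path(out_dir, "targets.csv")
  readr::write_csv(targets, targets_csv, progress = FALSE)

  for (tid in names(conf)) {
    write_model_csv(conf[[tid]], tid, file.path(sol_dir, paste0(tid, ".csv")))
  }

  groups <- c(near = "alpha", mid = "beta", decoy = "gamma")
  sig <- c(alpha = 0.5, beta = 2.0)
  for (g in groups) {
    gdir <- file.path(sub_dir, g)
    dir.create(gdir, showWarnings = FALSE)
    for (ti in seq_along(conf)) {
      tid <- names(conf)[ti]
      ref <- conf[[tid]][[1]]
      models <- lapply(1:5, function(m) {
        s <- base_seed + 100L * ti + 10L * m + match(g, groups)
        if (g == "gamma") {
          ch <- generate_chain(chain_length(ref), "coil", seed = s)
          ch$code <- ref$code
          ch
        } else {
          # spread models across the alternative conformations so the
          # best-over-solutions rule is exercised on T2
          src <- conf[[tid]][[1 + (m - 1) %% length(conf[[tid]])]]
          perturb_chain(src, sig[[g]], seed = s)
        }
      })
      write_model_csv(models, tid, file.path(gdir, paste0(tid, ".csv")))
    }
  }

  ens_base <- conf$T1[[1]]
  ens_sigma <- c(protenix = 1.0, tbm = 1.5, boltz = 2.5)
  for (src in names(ens_sigma)) {
    for (m in 1:5) {
      ch <- perturb_chain(ens_base, ens_sigma[[src]],
                          seed = base_seed + 1000L * match(src, names(ens_sigma)) + m)
      write_c1_chain(ch, file.path(ens_dir, sprintf("%s_%d.pdb", src, m)))
    }
  }

  invisible(list(targets_csv = targets_csv, solutions_dir = sol_dir,
                 submissions_dir = sub_dir, ensemble_dir = ens_dir,
                 groups = unname(groups), targets = targets))
}
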