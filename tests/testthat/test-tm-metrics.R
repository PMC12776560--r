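test_that("d0_of reproduces the piecewise rule and the closed form", {
  expect_equal(d0_of(10), 0.3)
  expect_equal(d0_of(13), 0.4)
  expect_equal(d0_of(17), 0.5)
  expect_equal(d0_of(22), 0.6)
  expect_equal(d0_of(26), 0.7)
  expect_equal(d0_of(30), 0.6 * sqrt(29.5) - 2.5)
  # band edges
  expect_equal(d0_of(c(11, 12, 15, 16, 19, 20, 23, 24, 29)),
               c(0.3, 0.4, 0.4, 0.5, 0.5, 0.6, 0.6, 0.7, 0.7))
  expect_gt(d0_of(30), 0.7)  # closed form continues above the last band
  expect_error(d0_of(0), class = "rnascore_input_error")
})

test_that("tm_fixed evaluates the raw TM sum for a fixed pairing", {
  ch <- generate_chain(20, "helix", seed = 31)
  al <- tm_alignment(1:20, 1:20)
  expect_equal(tm_fixed(ch, ch, al), 1.0)

  # a single aligned pair at distance exactly d0 contributes 1/(2 Lref)
  L <- 20
  d0 <- d0_of(L)
  a <- coord_chain(1, "A", x = 0, y = 0, z = 0)
  b <- coord_chain(1, "A", x = d0, y = 0, z = 0)
  expect_equal(tm_fixed(a, b, tm_alignment(1, 1), lref = L, d0 = d0),
               1 / (2 * L))

  # far-apart pairs contribute nothing
  far <- ch
  far$x <- far$x + 200 * d0_of(20)
  expect_lt(tm_fixed(far, ch, al), 1e-3)

  # unsolved aligned positions are an error
  holed <- ch
  holed$x[3] <- holed$y[3] <- holed$z[3] <- NA_real_
  expect_error(tm_fixed(holed, ch, al), class = "rnascore_unscorable")
})

test_that("alignment maps must be strictly monotone and in range", {
  expect_error(tm_alignment(c(1, 3, 2), c(1, 2, 3)), class = "rnascore_input_error")
  expect_error(tm_alignment(c(1, 2, 3), c(2, 2, 3)), class = "rnascore_input_error")
  ch <- generate_chain(5, "helix", seed = 1)
  expect_error(tm_fixed(ch, ch, tm_alignment(c(1, 6), c(1, 2))),
               class = "rnascore_input_error")
})

test_that("optimize_superposition maximizes TM for the fixed pairing", {
  ch <- generate_chain(15, "coil", seed = 41)
  moved <- apply_transform(test_transform(), ch)
  al <- tm_alignment(1:15, 1:15)
  res <- optimize_superposition(moved, ch, al)
  expect_s3_class(res, "tm_result")
  expect_equal(res$mode, "fixed")
  expect_equal(res$tm, 1.0, tolerance = 1e-6)

  # 8 residues with one displaced 50 A: matches the exhaustive-subset oracle
  base <- generate_chain(8, "coil", seed = 42)
  bad <- base
  bad$x[5] <- bad$x[5] + 50
  al8 <- tm_alignment(1:8, 1:8)
  res8 <- optimize_superposition(bad, base, al8)
  A <- cbind(bad$x, bad$y, bad$z)
  B <- cbind(base$x, base$y, base$z)
  oracle <- rnascore:::cpp_subset_superposition_oracle(A, B, 8, d0_of(8))
  expect_equal(res8$tm, oracle, tolerance = 1e-6)

  # never worse than the single whole-pairing Kabsch superposition
  for (i in 1:5) {
    m <- perturb_chain(base, 2, seed = 50 + i)
    fit <- kabsch(cbind(m$x, m$y, m$z), B)
    whole <- tm_fixed(m, base, al8, transform = fit)
    expect_gte(optimize_superposition(m, base, al8)$tm, whole - 1e-9)
  }
  expect_error(optimize_superposition(ch, ch, tm_alignment(1:2, 1:2)),
               class = "rnascore_input_error")
})

test_that("the large-pairing refinement heuristic also beats the whole-set fit", {
  base <- generate_chain(40, "helix", seed = 43)
  bad <- base
  bad$x[10:13] <- bad$x[10:13] + 30   # a displaced loop
  al <- tm_alignment(1:40, 1:40)
  res <- optimize_superposition(bad, base, al)
  B <- cbind(base$x, base$y, base$z)
  fit <- kabsch(cbind(bad$x, bad$y, bad$z), B)
  whole <- tm_fixed(bad, base, al, transform = fit)
  expect_gt(res$tm, whole + 0.01)  # outlier rejection must help here
})

test_that("tm_score forces sequence correspondence and handles unsolved residues", {
  ch <- generate_chain(25, "coil", seed = 51)
  expect_equal(tm_score(ch, ch)$tm, 1.0, tolerance = 1e-9)

  ref <- ch
  ref$x[c(4, 9)] <- ref$y[c(4, 9)] <- ref$z[c(4, 9)] <- NA_real_
  res <- tm_score(ch, ref)
  expect_equal(res$lref, 23)       # Lref excludes unsolved reference residues
  expect_equal(res$lalign, 23)
  expect_false(any(res$alignment$ref_pos %in% c(4, 9)))
  expect_equal(res$tm, 1.0, tolerance = 1e-9)

  expect_error(tm_score(generate_chain(5, "coil", seed = 1), ch),
               class = "rnascore_input_error")
})

test_that("tm_align is exact on tiny chains (full-enumeration oracle)", {
  for (i in 1:30) {
    pair <- random_chain_pair(i)
    sa <- rnascore:::solved_coords(pair$a)
    sb <- rnascore:::solved_coords(pair$b)
    lref <- solved_length(pair$b)
    oracle <- rnascore:::cpp_tm_align_oracle(sa$xyz, sb$xyz, lref, d0_of(lref))
    expect_equal(tm_align(pair$a, pair$b)$tm, oracle, tolerance = 1e-6)
  }
})

test_that("tm_align ignores residue numbering and recovers rigid copies", {
  ch <- generate_chain(30, "two_helix_bend", seed = 61, bend_angle = 75)
  moved <- apply_transform(test_transform(), ch)
  expect_equal(tm_align(moved, ch)$tm, 1.0, tolerance = 1e-6)

  shifted <- moved
  shifted$seq_id <- shifted$seq_id + 5L
  expect_equal(tm_align(shifted, ch)$tm, tm_align(moved, ch)$tm)

  short <- generate_chain(3, "coil", seed = 1)
  short$x[1] <- short$y[1] <- short$z[1] <- NA_real_
  expect_error(tm_align(short, ch), class = "rnascore_unscorable")
})

test_that("TM metric axioms hold across random pairs", {
  for (i in 1:12) {
    set.seed(700 + i)
    n <- sample(15:30, 1)
    a <- generate_chain(n, "coil", seed = 3000 + i)
    b <- perturb_chain(a, runif(1, 0.5, 4), seed = 4000 + i)
    res_al <- tm_align(b, a)
    res_sc <- tm_score(b, a)
    # free alignment can only help: identity pairing is in the candidate set
    expect_gte(res_al$tm, res_sc$tm - 1e-9)
    # bounds
    for (r in list(res_al, res_sc)) {
      expect_gt(r$tm, 0)
      expect_lte(r$tm, r$lalign / r$lref + 1e-12)
      # result is recomputable from its own alignment + superposition
      expect_equal(recompute_tm(r, b, a), r$tm, tolerance = 1e-9)
    }
    # rigid invariance of both inputs
    tr <- test_transform(angle = 360 * runif(1), shift = rnorm(3, sd = 20))
    expect_equal(tm_align(apply_transform(tr, b), a)$tm, res_al$tm,
                 tolerance = 1e-6)
    expect_equal(tm_align(b, apply_transform(tr, a))$tm, res_al$tm,
                 tolerance = 1e-6)
  }
})

test_that("tm_align normalizes by the reference (documented asymmetry)", {
  a <- generate_chain(20, "coil", seed = 81)
  b <- generate_chain(35, "helix", seed = 82)
  res <- tm_align(a, b)
  expect_equal(res$lref, 35)
  expect_equal(tm_align(b, a)$lref, 20)
})

test_that("rmsd_c1 matches the isotropic-noise expectation", {
  ch <- generate_chain(200, "helix", seed = 91)
  expect_equal(rmsd_c1(ch, ch), 0, tolerance = 1e-9)
  moved <- apply_transform(test_transform(), ch)
  expect_equal(rmsd_c1(moved, ch), 0, tolerance = 1e-7)
  sigma <- 1.5
  pert <- perturb_chain(ch, sigma, seed = 92)
  expect_equal(rmsd_c1(pert, ch), sigma * sqrt(3), tolerance = 0.25)
})

test_that("tidy/glance/autoplot expose the result components", {
  a <- generate_chain(20, "helix", seed = 95)
  b <- perturb_chain(a, 1, seed = 96)
  res <- tm_align(b, a)
  td <- tidy(res)
  expect_named(td, c("model_pos", "ref_pos", "distance", "contribution"))
  expect_equal(sum(td$contribution), res$tm, tolerance = 1e-9)
  gl <- glance(res)
  expect_equal(gl$tm, res$tm)
  expect_s3_class(autoplot(res), "ggplot")
})
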