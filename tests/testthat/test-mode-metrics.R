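# Mode-shape scoring and labeling.

test_that("synthetic pure fields score high in their own category only", {
  cg <- ring_cg("r1c")
  cats <- c("O_T", "O_R", "I_T", "zigzag", "spiderlike", "mixed_spiderlike")
  for (cat_ in cats) {
    v <- synthetic_mode_field(cg, "ring", cat_)
    sc <- ring_mode_scores(v, cg)
    expect_gte(sc[[cat_]], 0.9)
    expect_lte(max(sc[setdiff(names(sc), cat_)]), 0.1)
  }
})

test_that("synthetic cage fields score high in their own category only", {
  cg <- mini_fixture()$cg
  for (cat_ in c("O_B", "L_B", "torsional")) {
    v <- synthetic_mode_field(cg, "buckyball", cat_)
    sc <- ball_mode_scores(v, cg)
    expect_gte(sc[[cat_]], 0.9)
    expect_lte(max(sc[setdiff(names(sc), cat_)]), 0.1)
  }
  # a rigid rotation has no radial projection at all
  b <- cg$beads
  P <- sweep(as.matrix(b[, c("x", "y", "z")]), 2,
             colMeans(as.matrix(b[, c("x", "y", "z")])))
  rot <- cbind(-P[, 2], P[, 1], 0)
  sc <- ball_mode_scores(as.numeric(t(rot)), cg)
  expect_lt(sc[["O_B"]], 1e-10)
  expect_lt(sc[["L_B"]], 1e-10)
})

test_that("synthetic tile fields score high in their own category only", {
  cg <- tile_cg()
  for (cat_ in c("bending", "tweezer", "sticky_bend", "sticky_twist")) {
    v <- synthetic_mode_field(cg, "tile", cat_)
    sc <- tile_mode_scores(v, cg)
    expect_gte(sc[[cat_]], 0.9)
    expect_lte(max(sc[setdiff(names(sc), cat_)]), 0.11)
  }
})

test_that("scores are invariant to mode sign and scale", {
  cg <- ring_cg("r1c")
  ms <- ring_modes("r1c")
  v <- ms$vectors[, ms$zero_modes + 1]
  s1 <- ring_mode_scores(v, cg)
  s2 <- ring_mode_scores(-2.7 * v, cg)
  expect_equal(s1, s2, tolerance = 1e-12)
})

test_that("scores are invariant under the assembly's symmetry group", {
  cg <- ring_cg("r1c")
  ms <- ring_modes("r1c")
  part <- partition_by_symmetry(cg, cyclic_group(12))
  R <- cyclic_group(12)$rotations[[2]]
  v <- ms$vectors[, ms$zero_modes + 1]
  # rotate the displacement field with the structure: bead j of copy i
  # takes the rotated displacement of bead j of copy i-1
  D <- t(matrix(v, 3))
  D2 <- D
  for (i in 1:12) {
    src <- part$idx[, if (i == 1) 12 else i - 1]
    D2[part$idx[, i], ] <- D[src, ] %*% t(R)
  }
  s1 <- ring_mode_scores(v, cg)
  s2 <- ring_mode_scores(as.numeric(t(D2)), cg)
  expect_equal(s1, s2, tolerance = 1e-8)
})

test_that("degenerate pairs are labeled stably under remixing", {
  cg <- ring_cg("r1c")
  ms <- ring_modes("r1c")
  lam <- ms$lambda[-(1:ms$zero_modes)]
  dg <- which(abs(diff(lam)) < 1e-6 * pmax(abs(lam[-1]), 1e-30))[1]
  skip_if(is.na(dg), "no degenerate pair found")
  pair <- ms$vectors[, ms$zero_modes + c(dg, dg + 1)]
  th <- 0.83
  mix <- pair %*% matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  s1 <- ring_mode_scores(pair, cg)
  s2 <- ring_mode_scores(mix, cg)
  expect_equal(s1, s2, tolerance = 1e-8)
})

test_that("labeling skips rigid modes and applies the mixed margin", {
  ms <- ring_modes("r1c")
  expect_length(ms$labels, 10)
  expect_equal(nrow(ms$scores), 10)
  # mixed labels appear exactly where the top-two margin is under threshold
  for (r in seq_len(nrow(ms$scores))) {
    top <- sort(ms$scores[r, ], decreasing = TRUE)
    if (ms$labels[r] == "mixed") {
      expect_lt(top[1] - top[2], 0.15)
    } else {
      expect_identical(ms$labels[r], names(top)[1])
    }
  }
  expect_error(ring_mode_scores(ms$vectors[, 7], toy_fixture(3)$cg),
               class = "dnanma_unsupported_structure")
})
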