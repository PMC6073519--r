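# Symmetry-constrained reduction: partitioning, coupling blocks, the
# reduced eigenproblem, and expansion back to the full assembly.

test_that("partitioning verifies subunit congruence", {
  fx <- toy_fixture(4)
  part <- partition_by_symmetry(fx$cg, fx$meta$group)
  expect_equal(part$q, 4L)
  expect_equal(part$q * part$m, nrow(fx$cg$beads))
  expect_error(partition_by_symmetry(fx$cg, cyclic_group(5)),
               class = "dnanma_partition_error")
  # perturbing one bead breaks the congruence check
  cg2 <- fx$cg
  cg2$beads$x[cg2$beads$copy == 2][1] <- cg2$beads$x[cg2$beads$copy == 2][1] + 0.1
  expect_error(partition_by_symmetry(cg2, fx$meta$group),
               class = "dnanma_partition_error")
})

test_that("coupling blocks reflect the cycle adjacency", {
  fx <- toy_fixture(4)
  part <- partition_by_symmetry(fx$cg, fx$meta$group)
  sys <- assemble_stiffness(fx$cg)
  blocks <- extract_coupling_blocks(sys$K, part)
  expect_setequal(names(blocks$K1i), c("2", "4"))   # nearest neighbors only
  # block-row translational invariance: K11 + sum K1i annihilates a
  # uniform translation of the whole assembly restricted to row 1
  for (a in 1:3) {
    tvec <- rep(0, 3 * part$m); tvec[seq(a, 3 * part$m, by = 3)] <- 1
    resid <- blocks$K11 %*% tvec
    for (bl in blocks$K1i) resid <- resid + bl %*% tvec
    expect_lt(max(abs(resid)), 1e-8 * max(fx$cg$springs$k))
  }
})

test_that("block extraction and direct spring assembly agree", {
  fx <- toy_fixture(4)
  part <- partition_by_symmetry(fx$cg, fx$meta$group)
  sys <- assemble_stiffness(fx$cg)
  b1 <- extract_coupling_blocks(sys$K, part)
  b2 <- dnanma:::.reduced_blocks_direct(fx$cg, part)
  expect_lt(max(abs(b1$K11 - b2$K11)), 1e-9)
  for (nm in names(b1$K1i)) {
    expect_lt(max(abs(b1$K1i[[nm]] - b2$K1i[[nm]])), 1e-9)
  }
})

test_that("reduction with the identity group reproduces the full problem", {
  fx <- toy_fixture(3)
  cg1 <- fx$cg
  cg1$beads$copy <- 1L
  part <- partition_by_symmetry(cg1, cyclic_group(1))
  sys <- assemble_stiffness(cg1)
  blocks <- extract_coupling_blocks(sys$K, part)
  red <- reduce_symmetry(blocks, part, sys$M)
  expect_lt(max(abs(red$K_red - sys$K)), 1e-12)
  ms_red <- solve_scenm(red, n_modes = 12)
  ms_full <- solve_modes(cg1, n_modes = 12)
  expect_equal(ms_red$lambda, ms_full$lambda, tolerance = 1e-8)
})

test_that("the reduced operator annihilates only group-invariant rigid motions", {
  fx <- toy_fixture(4)
  part <- partition_by_symmetry(fx$cg, fx$meta$group)
  sys <- assemble_stiffness(fx$cg)
  red <- reduce_symmetry(extract_coupling_blocks(sys$K, part), part, sys$M)
  expect_lt(red$asymmetry, 1e-8)
  expect_equal(nrow(red$K_red), 3 * part$m)          # cost reduced by 1/q
  tz <- rep(c(0, 0, 1), part$m)
  tx <- rep(c(1, 0, 0), part$m)
  kmax <- max(fx$cg$springs$k)
  expect_lt(max(abs(red$K_red %*% tz)), 1e-8 * kmax)  # z is the C4 axis
  expect_gt(max(abs(red$K_red %*% tx)), 1e-4 * kmax)  # x is not invariant
})

test_that("SCENM eigenpairs match the dense full spectrum on toy rings", {
  for (q in c(3, 4, 6)) {
    fx <- toy_fixture(q)
    expect_lte(nrow(fx$cg$beads), 500)
    sm <- cached(paste0("scenm_c", q),
                 scenm_modes(fx$cg, fx$meta$group, n_modes = 12))
    full <- cached(paste0("dense_c", q), dense_spectrum(fx$cg))
    lam_scale <- max(full)
    for (lam in sm$lambda) {
      rel <- min(abs(full - lam)) / max(abs(lam), 1e-8 * lam_scale)
      expect_lt(rel, 1e-6)
    }
    # expanded vectors satisfy the full eigen-equation
    expect_lt(max(sm$residuals), 1e-6)
  }
})

test_that("expanded cage modes repeat the subunit motion through the group", {
  msb <- ball_modes()
  cg <- ball_cg()
  expect_equal(msb$q, 60L)
  expect_equal(msb$m * msb$q, nrow(cg$beads))
  expect_lt(msb$asymmetry, 1e-8)
  expect_lt(max(msb$residuals), 1e-6)
  # the overall-breathing mode moves every subunit radially in phase
  ob <- which(msb$labels == "O_B")[1]
  expect_false(is.na(ob))
  v <- msb$vectors[, msb$zero_modes + ob]
  b <- cg$beads
  P <- sweep(as.matrix(b[, c("x", "y", "z")]), 2,
             colMeans(as.matrix(b[, c("x", "y", "z")])))
  rhat <- P / sqrt(rowSums(P^2))
  D <- t(matrix(v, 3))
  per_tile <- tapply(b$mass * rowSums(D * rhat), b$copy, sum)
  expect_true(all(per_tile > 0) || all(per_tile < 0))
})
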