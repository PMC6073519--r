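# Normal mode analysis: stiffness/mass assembly, eigensolution, rigid modes.

test_that("the dimer stiffness matrix has the closed-form spectrum", {
  fx <- generate_fixture("dimer")
  sys <- assemble_stiffness(fx$cg)
  ev <- sort(eigen(as.matrix(sys$K), symmetric = TRUE)$values)
  k <- fx$cg$springs$k[1]
  expect_equal(ev, c(0, 0, 0, 0, 0, 2 * k), tolerance = 1e-12)
})

test_that("the stiffness matrix annihilates rigid translations", {
  cg <- toy_fixture(3)$cg
  sys <- assemble_stiffness(cg)
  for (a in 1:3) {
    tvec <- rep(0, 3 * sys$n); tvec[seq(a, 3 * sys$n, by = 3)] <- 1
    expect_lt(max(abs(sys$K %*% tvec)), 1e-8 * max(cg$springs$k))
  }
})

test_that("assembled K equals the finite-difference Hessian of the pair potential", {
  # small irregular bead system with all three bond classes
  set.seed(42)
  beads <- data.frame(
    x = runif(6), y = runif(6), z = runif(6), mass = runif(6, 50, 300),
    nt = 1:6, strand = "t", ord = 1:6, copy = 1L, role = "toy",
    sticky = FALSE, bead = "P", base = "A", seg = "toy")
  springs <- data.frame(
    i = c(1, 2, 3, 4, 5, 1, 2), j = c(2, 3, 4, 5, 6, 4, 6),
    type = c("covalent", "covalent", "hydrogen", "covalent",
             "van_der_waals", "hydrogen", "van_der_waals"),
    k = c(700, 700, 70, 700, 7, 70, 7))
  xyz <- as.matrix(beads[, c("x", "y", "z")])
  springs$rest <- sqrt(rowSums((xyz[springs$i, ] - xyz[springs$j, ])^2))
  cg <- cg_model(beads, springs)
  K <- as.matrix(assemble_stiffness(cg)$K)
  # independent oracle: central-difference Hessian of
  # V = 1/2 sum k (||xi - xj|| - r0)^2 at the equilibrium coordinates
  V <- function(p) {
    pm <- matrix(p, ncol = 3, byrow = TRUE)
    d <- sqrt(rowSums((pm[springs$i, , drop = FALSE] -
                         pm[springs$j, , drop = FALSE])^2))
    0.5 * sum(springs$k * (d - springs$rest)^2)
  }
  p0 <- as.numeric(t(xyz))
  h <- 1e-5
  n3 <- length(p0)
  H <- matrix(0, n3, n3)
  for (a in seq_len(n3)) for (b in a:n3) {
    pa <- p0; pa[a] <- pa[a] + h; pa[b] <- pa[b] + h
    pb <- p0; pb[a] <- pb[a] + h; pb[b] <- pb[b] - h
    pc <- p0; pc[a] <- pc[a] - h; pc[b] <- pc[b] + h
    pd <- p0; pd[a] <- pd[a] - h; pd[b] <- pd[b] - h
    H[a, b] <- H[b, a] <- (V(pa) - V(pb) - V(pc) + V(pd)) / (4 * h^2)
  }
  expect_lt(max(abs(K - H)), 1e-6 * max(springs$k))
})

test_that("degenerate geometry raises an error", {
  beads <- data.frame(x = c(0, 0), y = 0, z = 0, mass = 10, nt = 1:2,
                      strand = "t", ord = 1:2, copy = 1L, role = "toy",
                      sticky = FALSE, bead = "P", base = "A", seg = "toy")
  springs <- data.frame(i = 1L, j = 2L, type = "covalent", k = 700, rest = 0)
  expect_error(assemble_stiffness(cg_model(beads, springs)),
               class = "dnanma_degenerate_geometry")
})

test_that("the mass matrix is the lumped diagonal", {
  cg <- toy_fixture(3)$cg
  M <- assemble_mass(cg)
  expect_equal(sum(M), 3 * total_mass(cg))
  expect_equal(M[1:3], rep(cg$beads$mass[1], 3))
  # kinetic energy of a uniform velocity field w
  w <- c(0.3, -1.2, 0.7)
  wv <- rep(w, nrow(cg$beads))
  expect_equal(0.5 * sum(M * wv^2), 0.5 * sum(w^2) * total_mass(cg))
})

test_that("the dimer mode solves at lambda = 2k/m", {
  fx <- generate_fixture("dimer")
  ms <- solve_modes(fx$cg, n_modes = 6)
  expect_equal(ms$zero_modes, fx$meta$zero_modes)
  expect_equal(max(ms$lambda), fx$meta$lambda_nonzero, tolerance = 1e-10)
})

test_that("a three-bead chain matches an independent dense solution", {
  beads <- data.frame(x = c(0, 0.5, 1.0), y = 0, z = 0,
                      mass = c(100, 150, 80), nt = 1:3, strand = "t",
                      ord = 1:3, copy = 1L, role = "toy", sticky = FALSE,
                      bead = "P", base = "A", seg = "toy")
  springs <- data.frame(i = c(1, 2), j = c(2, 3), type = "covalent",
                        k = 700, rest = 0.5)
  cg <- cg_model(beads, springs)
  # a straight 3-bead chain is transversely floppy, hence the warning
  expect_warning(ms <- solve_modes(cg, n_modes = 9), "zero modes")
  ora <- dense_spectrum(cg)
  nz <- ms$lambda[ms$lambda > 1e-8 * max(ms$lambda)]
  nz_o <- ora[ora > 1e-8 * max(ora)]
  expect_equal(nz, nz_o[seq_along(nz)], tolerance = 1e-9)
})

test_that("connected assembled structures have exactly six rigid modes", {
  for (key in c(3, 4)) {
    ms <- cached(paste0("toyms_c", key),
                 solve_modes(toy_fixture(key)$cg, n_modes = 14))
    expect_equal(ms$zero_modes, 6L)
    expect_true(all(ms$lambda[-(1:6)] > 0))
    expect_false(is.unsorted(ms$lambda))
  }
  msm <- cached("minims", suppressWarnings(solve_modes(mini_fixture()$cg,
                                                       n_modes = 10)))
  expect_equal(msm$zero_modes, 6L)
  expect_equal(ring_modes("r1c")$zero_modes, 6L)
})

test_that("a floppy chain warns of more than six zero modes", {
  fx <- generate_fixture("chain", size = 5)
  expect_warning(ms <- solve_modes(fx$cg, n_modes = 15),
                 "disconnected|zero modes")
  expect_equal(ms$zero_modes, fx$meta$zero_modes)
})

test_that("mode vectors are mass-orthonormal", {
  for (ms_cg in list(list(cached("toyms_c4", solve_modes(toy_fixture(4)$cg, n_modes = 14)),
                          toy_fixture(4)$cg),
                     list(ring_modes("r1c"), ring_cg("r1c")))) {
    ms <- ms_cg[[1]]; cg <- ms_cg[[2]]
    M <- assemble_mass(cg)
    G <- crossprod(ms$vectors, ms$vectors * M)
    expect_lt(max(abs(G - diag(ncol(G)))), 1e-8)
  }
})

test_that("sparse and dense eigensolution agree", {
  cg <- toy_fixture(4)$cg     # 3N under 1500
  dense <- solve_modes(cg, n_modes = 14, dense_limit = 1e6)
  sparse <- solve_modes(cg, n_modes = 14, dense_limit = 10)
  nz <- dense$lambda > 1e-8 * max(dense$lambda)
  expect_equal(sparse$lambda[nz], dense$lambda[nz], tolerance = 1e-8)
})

test_that("eigenvalues are invariant to bead relabeling and global rotation", {
  cg <- toy_fixture(3)$cg
  ms <- cached("toyms_c3", solve_modes(toy_fixture(3)$cg, n_modes = 14))
  set.seed(7)
  perm <- sample(nrow(cg$beads))
  cg2 <- cg
  cg2$beads <- cg$beads[perm, ]
  inv <- integer(length(perm)); inv[perm] <- seq_along(perm)
  cg2$springs$i <- inv[cg$springs$i]; cg2$springs$j <- inv[cg$springs$j]
  ms2 <- solve_modes(cg2, n_modes = 14)
  expect_equal(ms2$lambda, ms$lambda, tolerance = 1e-9)
  # rotating the whole structure leaves the spectrum unchanged
  R <- rotation_about(c(1, 2, 3), 0.7)
  cg3 <- cg
  pos <- as.matrix(cg$beads[, c("x", "y", "z")]) %*% t(R)
  cg3$beads$x <- pos[, 1]; cg3$beads$y <- pos[, 2]; cg3$beads$z <- pos[, 3]
  ms3 <- solve_modes(cg3, n_modes = 14)
  expect_equal(ms3$lambda, ms$lambda, tolerance = 1e-8)
})
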