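# Normal mode analysis: assembly of the stiffness and mass matrices and
# solution of the generalized eigenproblem K v = omega^2 M v.
#
# The pair potential V = 1/2 sum k_ij (||x_i - x_j|| - r_ij)^2 has, at the
# equilibrium geometry, the Hessian made of 3x3 blocks k_ij e e^T with e the
# unit inter-bead vector: added on the diagonal blocks and subtracted on the
# off-diagonal blocks.  K is kept in N/m at the interface; the conversion
# to amu/ps^2 happens inside the solver so that eigenvalues come out as
# omega^2 in (rad/ps)^2.

#' @importFrom Matrix sparseMatrix Diagonal Cholesky solve t diag crossprod
NULL

#' Assemble the sparse stiffness matrix
#'
#' @param cg A [cg_model()].
#' @return list with `K` (3N x 3N sparse symmetric, N/m), `M` (length-3N
#'   vector of per-coordinate masses, amu) and `n` (bead count); class
#'   `system_matrices`.
#' @export
assemble_stiffness <- function(cg) {
  b <- cg$beads; s <- cg$springs
  n <- nrow(b)
  if (any(s$rest <= 0)) abort_dnanma("zero-length spring", "dnanma_degenerate_geometry")
  xyz <- as.matrix(b[, c("x", "y", "z")])
  dv <- xyz[s$i, , drop = FALSE] - xyz[s$j, , drop = FALSE]
  e <- dv / s$rest
  # 3x3 block entries k * e_a * e_b for every spring
  rows <- cols <- vals <- vector("list", 9)
  idx <- 1
  for (a in 1:3) for (bb in 1:3) {
    kab <- s$k * e[, a] * e[, bb]
    ia <- 3 * (s$i - 1) + a; ib <- 3 * (s$i - 1) + bb
    ja <- 3 * (s$j - 1) + a; jb <- 3 * (s$j - 1) + bb
    rows[[idx]] <- c(ia, ja, ia, ja)
    cols[[idx]] <- c(ib, jb, jb, ib)
    vals[[idx]] <- c(kab, kab, -kab, -kab)
    idx <- idx + 1
  }
  K <- sparseMatrix(i = unlist(rows), j = unlist(cols), x = unlist(vals),
                    dims = c(3 * n, 3 * n), symmetric = FALSE)
  K <- (K + Matrix::t(K)) / 2        # numerically exact symmetrization
  structure(list(K = K, M = assemble_mass(cg), n = n, xyz = xyz),
            class = "system_matrices")
}

#' Assemble the diagonal mass matrix
#'
#' @param cg A [cg_model()].
#' @return Numeric vector of length 3N: each bead's lumped mass repeated
#'   for x, y, z (amu).
#' @export
assemble_mass <- function(cg) {
  m <- cg$beads$mass
  if (any(!is.finite(m)) || any(m <= 0)) {
    abort_dnanma("non-positive bead mass", "dnanma_invalid_model")
  }
  rep(m, each = 3)
}

# rigid-body basis (3 translations + 3 rotations) of a bead set, 3N x 6
.rigid_basis <- function(xyz) {
  n <- nrow(xyz)
  ctr <- colMeans(xyz)
  xc <- sweep(xyz, 2, ctr)
  B <- matrix(0, 3 * n, 6)
  for (a in 1:3) B[seq(a, 3 * n, by = 3), a] <- 1
  B[, 4] <- as.numeric(t(cbind(0, -xc[, 3], xc[, 2])))
  B[, 5] <- as.numeric(t(cbind(xc[, 3], 0, -xc[, 1])))
  B[, 6] <- as.numeric(t(cbind(-xc[, 2], xc[, 1], 0)))
  B
}

.modeset <- function(lambda, vectors, zero_tol) {
  ord <- order(lambda)
  lambda <- lambda[ord]; vectors <- vectors[, ord, drop = FALSE]
  thr <- zero_tol * max(abs(lambda), 1e-300)
  zero <- sum(lambda < thr)
  # deterministic sign convention: first significant component positive
  for (k in seq_len(ncol(vectors))) {
    v <- vectors[, k]
    lead <- which(abs(v) > 0.05 * max(abs(v)))[1]
    if (v[lead] < 0) vectors[, k] <- -v
  }
  omega <- sqrt(pmax(lambda, 0))
  structure(list(
    lambda = lambda, omega_radps = omega,
    freq_cm1 = omega * CM1_PER_RADPS,
    vectors = vectors, zero_modes = zero, labels = NULL
  ), class = "mode_set")
}

#' @export
print.mode_set <- function(x, ...) {
  cat("mode_set:", length(x$lambda), "modes,", x$zero_modes, "rigid-body modes\n")
  nonrigid <- if (x$zero_modes > 0) x$freq_cm1[-seq_len(x$zero_modes)] else x$freq_cm1
  cat("  first non-rigid frequencies (cm^-1):",
      paste(signif(utils::head(nonrigid, 5), 4), collapse = ", "), "\n")
  if (!is.null(x$labels)) {
    cat("  labels:", paste(utils::head(x$labels, 10), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Solve for the lowest normal modes
#'
#' Solves K v = lambda M v for the `n_modes` smallest eigenvalues.  Small
#' systems (3N below `dense_limit`) are diagonalized densely; larger ones
#' use shift-inverted Lanczos iterations (ARPACK) on the sparse
#' mass-weighted Hessian with a sparse Cholesky factorization.  Mode
#' vectors are returned mass-orthonormal (v' M v = I).
#'
#' @param sys A `system_matrices` object from [assemble_stiffness()], or a
#'   [cg_model()] (assembled on the fly).
#' @param n_modes Number of modes to return (including rigid-body modes).
#' @param zero_tol Relative threshold for classifying eigenvalues as
#'   rigid-body (zero) modes.
#' @param dense_limit Dense-solver threshold on matrix order 3N.
#' @param seed Seed for the iterative solver's start vector.
#' @return A `mode_set`: eigenvalues `lambda` (omega^2, rad^2/ps^2),
#'   `omega_radps`, `freq_cm1`, mass-orthonormal `vectors` (3N x n_modes),
#'   and `zero_modes` count.
#' @export
solve_modes <- function(sys, n_modes = 20,
                        zero_tol = dnanma_defaults()$zero_tol,
                        dense_limit = 3000, seed = 1L) {
  if (inherits(sys, "cg_model")) sys <- assemble_stiffness(sys)
  n3 <- 3 * sys$n
  n_modes <- min(n_modes, n3)
  dh <- 1 / sqrt(sys$M)
  Kt <- AMU_PS2_PER_NM * Matrix::t(Matrix::t(sys$K * dh) * dh)   # D^-1/2 K D^-1/2
  Kt <- (Kt + Matrix::t(Kt)) / 2
  if (n3 <= dense_limit) {
    eg <- eigen(as.matrix(Kt), symmetric = TRUE)
    lambda <- rev(eg$values)[seq_len(n_modes)]
    U <- eg$vectors[, rev(seq_len(n3))[seq_len(n_modes)], drop = FALSE]
  } else {
    # shift-inverted Lanczos with the six rigid-body modes deflated
    # analytically (they are known exactly from the geometry); without
    # deflation the rigid cluster at 1/sigma swamps the soft elastic modes
    Bq <- qr.Q(qr(.rigid_basis(sys$xyz) * sqrt(sys$M)))
    sigma <- 1e-6 * mean(Matrix::diag(Kt))
    ch <- Cholesky(Kt + sigma * Diagonal(n3), LDL = FALSE, perm = TRUE)
    proj <- function(x) x - Bq %*% crossprod(Bq, x)
    fn <- function(x, extra) {
      as.numeric(proj(Matrix::solve(ch, proj(x), system = "A")))
    }
    nev <- max(1L, n_modes - 6L)
    set.seed(seed)
    ar <- igraph::arpack(fn, sym = TRUE,
                         options = list(n = n3, nev = nev,
                                        ncv = min(n3, max(4 * nev, 40)),
                                        which = "LA", maxiter = 3000))
    if (any(!is.finite(ar$values))) {
      abort_dnanma("eigensolver failed to converge", "dnanma_numerical_error")
    }
    lambda <- c(rep(0, 6), 1 / ar$values - sigma)
    U <- cbind(Bq, qr.Q(qr(as.matrix(ar$vectors))))
    if (length(lambda) > n_modes) {   # caller asked for fewer than 7 modes
      keep <- order(lambda)[seq_len(n_modes)]
      lambda <- lambda[keep]; U <- U[, keep, drop = FALSE]
    }
  }
  V <- U * dh
  ms <- .modeset(lambda, V, zero_tol)
  if (ms$zero_modes > 6) {
    warning("more than 6 zero modes: the spring network is disconnected")
  }
  ms$n_beads <- sys$n
  ms
}
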