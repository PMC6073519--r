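# Symmetry-constrained reduction: solve the eigenproblem of a q-copy
# symmetric assembly on a single 3m-dimensional subunit block.
#
# For a displacement field that repeats the first subunit's motion through
# the group rotations (Delta_i = R_i Delta_1), the action of the full
# stiffness on subunit 1 reduces to
#     K_reduced = K_{1,1} + K_{1,2} R_2 + ... + K_{1,q} R_q,
# with M_reduced the subunit-1 mass block.  Eigenpairs of the reduced
# problem expand back to full-assembly modes via Delta_i = R_i Delta_1;
# this captures the totally symmetric representation (every subunit
# repeating the same motion), which is where the cage breathing and
# torsional modes live.

#' Partition a coarse model by its symmetry group
#'
#' Verifies that the beads split into `q` congruent subunits with matching
#' local ordering: bead j of subunit i must equal rotation i applied to
#' bead j of subunit 1.
#'
#' @param cg A [cg_model()] built from a symmetric assembly with recorded
#'   tile copy indices.
#' @param group A `symmetry_group` whose order matches the copy count.
#' @param tol Position tolerance (nm) for the congruence check.
#' @return A `subunit_partition`: list with q, m, and the per-subunit bead
#'   index matrix `idx` (m x q).
#' @export
partition_by_symmetry <- function(cg, group, tol = 1e-6) {
  b <- cg$beads
  copies <- sort(unique(b$copy))
  q <- group$order
  if (length(copies) != q) {
    abort_dnanma(sprintf("group order %d does not match copy count %d",
                         q, length(copies)), "dnanma_partition_error")
  }
  n <- nrow(b)
  if (n %% q != 0) abort_dnanma("bead count not divisible by group order",
                                "dnanma_partition_error")
  m <- n %/% q
  idx <- matrix(NA_integer_, m, q)
  for (i in seq_len(q)) {
    ci <- which(b$copy == copies[i])
    if (length(ci) != m) abort_dnanma("unequal subunit sizes", "dnanma_partition_error")
    idx[, i] <- ci
  }
  x1 <- as.matrix(b[idx[, 1], c("x", "y", "z")])
  for (i in seq_len(q)) {
    xi <- as.matrix(b[idx[, i], c("x", "y", "z")])
    err <- sqrt(rowSums((xi - x1 %*% t(group$rotations[[i]]))^2))
    if (max(err) > tol) {
      abort_dnanma(sprintf(
        "subunit %d bead %d deviates %.2e nm from the rotated subunit 1",
        i, which.max(err), max(err)), "dnanma_partition_error")
    }
    if (max(abs(b$mass[idx[, i]] - b$mass[idx[, 1]])) > 1e-9) {
      abort_dnanma("subunit masses do not match", "dnanma_partition_error")
    }
  }
  structure(list(q = q, m = m, idx = idx, group = group),
            class = "subunit_partition")
}

# coordinate (3N-space) indices of subunit i
.coord_idx <- function(part, i) {
  as.vector(t(outer(part$idx[, i] - 1L, 1:3, function(a, b) 3 * a + b)))
}

#' Extract subunit coupling blocks from the full stiffness matrix
#'
#' @param K Full 3N x 3N stiffness (from [assemble_stiffness()]).
#' @param part A `subunit_partition`.
#' @return list with `K11` and `K1i` (named list over coupled subunits
#'   i >= 2; only blocks with nonzero entries are kept).
#' @export
extract_coupling_blocks <- function(K, part) {
  i1 <- .coord_idx(part, 1)
  K11 <- K[i1, i1, drop = FALSE]
  K1i <- list()
  for (i in seq_len(part$q)[-1]) {
    blk <- K[i1, .coord_idx(part, i), drop = FALSE]
    if (length(blk@x) && max(abs(blk@x)) > 0) K1i[[as.character(i)]] <- blk
  }
  list(K11 = K11, K1i = K1i)
}

# assemble the subunit-1 row blocks directly from springs incident to
# subunit 1, without materializing the full K
.reduced_blocks_direct <- function(cg, part) {
  b <- cg$beads; s <- cg$springs
  n <- nrow(b); m <- part$m; q <- part$q
  sub_of <- integer(n); loc_of <- integer(n)
  for (i in seq_len(q)) { sub_of[part$idx[, i]] <- i; loc_of[part$idx[, i]] <- seq_len(m) }
  xyz <- as.matrix(b[, c("x", "y", "z")])
  tri <- function() list(i = integer(0), j = integer(0), x = numeric(0))
  acc <- list(); acc[["1"]] <- tri()
  touch <- s[sub_of[s$i] == 1L | sub_of[s$j] == 1L, , drop = FALSE]
  for (r in seq_len(nrow(touch))) {
    i <- touch$i[r]; j <- touch$j[r]
    e <- (xyz[i, ] - xyz[j, ]) / touch$rest[r]
    blk <- touch$k[r] * (e %o% e)
    pairs <- list(c(i, i, 1), c(j, j, 1), c(i, j, -1), c(j, i, -1))
    for (p in pairs) {
      a <- p[1]; bb <- p[2]; sgn <- p[3]
      if (sub_of[a] != 1L) next
      tgt <- as.character(sub_of[bb])
      if (is.null(acc[[tgt]])) acc[[tgt]] <- tri()
      ro <- 3 * (loc_of[a] - 1); co <- 3 * (loc_of[bb] - 1)
      acc[[tgt]]$i <- c(acc[[tgt]]$i, rep(ro + 1:3, 3))
      acc[[tgt]]$j <- c(acc[[tgt]]$j, rep(co + 1:3, each = 3))
      acc[[tgt]]$x <- c(acc[[tgt]]$x, sgn * as.numeric(blk))
    }
  }
  out <- lapply(acc, function(t3)
    sparseMatrix(i = t3$i, j = t3$j, x = t3$x, dims = c(3 * m, 3 * m)))
  list(K11 = out[["1"]], K1i = out[names(out) != "1"])
}

#' Form the reduced stiffness and mass
#'
#' @param blocks list with `K11` and `K1i` as returned by
#'   [extract_coupling_blocks()].
#' @param part A `subunit_partition` (supplies the rotations).
#' @param M Full mass vector (3N) or subunit mass vector (3m).
#' @return A `reduced_system`: `K_red` (symmetrized), `M_red`, the
#'   asymmetry residual of the raw reduced operator, q, m.
#' @export
reduce_symmetry <- function(blocks, part, M) {
  m <- part$m; q <- part$q
  if (length(M) == 3 * m * q) M <- M[.coord_idx(part, 1)]
  stopifnot(length(M) == 3 * m)
  K_red <- blocks$K11
  for (nm in names(blocks$K1i)) {
    i <- as.integer(nm)
    Ri <- kronecker(Diagonal(m), part$group$rotations[[i]])
    K_red <- K_red + blocks$K1i[[nm]] %*% Ri
  }
  K_red <- as(K_red, "generalMatrix")
  asym <- sqrt(sum((K_red - Matrix::t(K_red))^2)) / max(sqrt(sum(K_red^2)), 1e-300)
  structure(list(
    K_red = (K_red + Matrix::t(K_red)) / 2, M_red = M,
    asymmetry = as.numeric(asym), q = q, m = m, part = part
  ), class = "reduced_system")
}

#' Solve the reduced eigenproblem and expand to full-assembly modes
#'
#' Solves the 3m-dimensional reduced problem, expands each mode through the
#' group rotations (subunit i moves as rotation i applied to subunit 1's
#' motion), mass-normalizes on the full assembly, and (when the full
#' stiffness is supplied) verifies each eigenvalue through the Rayleigh
#' quotient and residual of its expanded vector.
#'
#' @param red A `reduced_system`.
#' @param n_modes Number of modes to return.
#' @param K_full,M_full Optional full-assembly stiffness (N/m) and 3N mass
#'   vector for residual verification.
#' @param zero_tol Rigid-mode threshold, as in [solve_modes()].
#' @return A `mode_set` on the full assembly, with `residuals` (when
#'   verified), `asymmetry`, `q` and `m` in the object.
#' @export
solve_scenm <- function(red, n_modes = 20, K_full = NULL, M_full = NULL,
                        zero_tol = dnanma_defaults()$zero_tol) {
  m3 <- 3 * red$m
  n_modes <- min(n_modes, m3)
  dh <- 1 / sqrt(red$M_red)
  Kt <- AMU_PS2_PER_NM * Matrix::t(Matrix::t(red$K_red * dh) * dh)
  eg <- eigen(as.matrix((Kt + Matrix::t(Kt)) / 2), symmetric = TRUE)
  sel <- rev(seq_len(m3))[seq_len(n_modes)]
  lambda <- eg$values[sel]
  U <- eg$vectors[, sel, drop = FALSE]
  V1 <- U * dh                      # subunit-1 modes, M1-orthonormal
  part <- red$part
  N3 <- 3 * red$m * red$q
  V <- matrix(0, N3, n_modes)
  for (i in seq_len(red$q)) {
    Ri <- part$group$rotations[[i]]
    ci <- .coord_idx(part, i)
    for (k in seq_len(n_modes)) {
      V[ci, k] <- as.numeric(Ri %*% matrix(V1[, k], 3, red$m))
    }
  }
  V <- V / sqrt(red$q)              # full-assembly mass normalization
  ms <- .modeset(lambda, V, zero_tol)
  ms$asymmetry <- red$asymmetry
  ms$q <- red$q; ms$m <- red$m
  ms$n_beads <- red$m * red$q
  if (!is.null(K_full) && !is.null(M_full)) {
    resid <- numeric(ncol(ms$vectors))
    lam_ref <- max(abs(ms$lambda))
    nz <- ms$lambda[ms$lambda > zero_tol * lam_ref]
    # rigid modes (lambda ~ 0) are checked against the softest elastic
    # eigenvalue instead of their own vanishing one
    lam_guard <- if (length(nz)) min(nz) else lam_ref
    for (k in seq_len(ncol(ms$vectors))) {
      v <- ms$vectors[, k]
      Kv <- AMU_PS2_PER_NM * as.numeric(K_full %*% v)
      Mv <- M_full * v
      lam <- sum(v * Kv) / sum(v * Mv)
      denom <- sqrt(sum(Mv^2)) * max(abs(lam), lam_guard, 1e-300)
      resid[k] <- sqrt(sum((Kv - lam * Mv)^2)) / denom
    }
    ms$residuals <- resid
  }
  ms
}

#' One-call SCENM pipeline
#'
#' @param cg A [cg_model()] of a symmetric assembly.
#' @param group Its `symmetry_group`.
#' @param n_modes Number of modes.
#' @param verify Verify expanded modes against the full stiffness.
#' @param direct Assemble the subunit blocks directly from springs instead
#'   of extracting them from the full matrix.
#' @return A `mode_set` on the full assembly.
#' @export
scenm_modes <- function(cg, group, n_modes = 20, verify = TRUE, direct = FALSE) {
  part <- partition_by_symmetry(cg, group)
  sys <- if (verify || !direct) assemble_stiffness(cg) else NULL
  blocks <- if (direct) .reduced_blocks_direct(cg, part)
            else extract_coupling_blocks(sys$K, part)
  M <- if (is.null(sys)) rep(cg$beads$mass, each = 3) else sys$M
  red <- reduce_symmetry(blocks, part, M)
  solve_scenm(red, n_modes,
              K_full = if (verify) sys$K else NULL,
              M_full = if (verify) sys$M else NULL)
}
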