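# Finite rotation groups used to place tile copies: cyclic groups about z
# for the rings, and the icosahedral / tetrahedral rotation groups for the
# cage assemblies.  The icosahedral group is generated programmatically from
# two generators (a 2-fold about z and a 5-fold about an icosahedron
# vertex); only the abstract group matters, not any particular structure.

#' Cyclic symmetry group about an axis
#'
#' @param q Group order (>= 1).
#' @param axis Rotation axis (default z).
#' @return A `symmetry_group`: list with `order`, `rotations` (list of 3x3
#'   matrices, identity first) and `name`.
#' @export
cyclic_group <- function(q, axis = c(0, 0, 1)) {
  stopifnot(q >= 1)
  rots <- lapply(seq_len(q) - 1L, function(k) rotation_about(axis, 2 * pi * k / q))
  structure(list(order = as.integer(q), rotations = rots,
                 name = sprintf("C%d", q)),
            class = "symmetry_group")
}

# generate the closure of a set of rotation matrices (finite groups only)
.group_closure <- function(gens, max_order = 120, tol = 1e-9) {
  elems <- list(diag(3))
  sig <- function(m) {
    m <- round(m, 6)
    m[abs(m) < 1e-9] <- 0      # avoid distinct "-0"/"0" signatures
    paste(sprintf("%.6f", m), collapse = ",")
  }
  seen <- new.env(parent = emptyenv())
  assign(sig(diag(3)), TRUE, envir = seen)
  queue <- list(diag(3))
  while (length(queue)) {
    m <- queue[[1]]; queue <- queue[-1]
    for (g in gens) {
      nm <- g %*% m
      s <- sig(nm)
      if (!exists(s, envir = seen)) {
        assign(s, TRUE, envir = seen)
        elems[[length(elems) + 1]] <- nm
        queue[[length(queue) + 1]] <- nm
        if (length(elems) > max_order) stop("group closure exceeded max_order")
      }
    }
  }
  elems
}

# icosahedron vertices (circumradius 1), z axis a 2-fold axis
.icosahedron_vertices <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    cbind(0, c(1, 1, -1, -1), c(phi, -phi, phi, -phi)),
    cbind(c(1, 1, -1, -1), c(phi, -phi, phi, -phi), 0),
    cbind(c(phi, -phi, phi, -phi), 0, c(1, 1, -1, -1))
  )
  v / sqrt(1 + phi^2)
}

#' Icosahedral rotation group (order 60)
#'
#' @return A `symmetry_group` of order 60 (identity first).
#' @export
icosahedral_group <- function() {
  v <- .icosahedron_vertices()
  g1 <- rotation_about(c(0, 0, 1), pi)          # 2-fold about z
  g2 <- rotation_about(v[1, ], 2 * pi / 5)      # 5-fold about a vertex
  elems <- .group_closure(list(g1, g2), max_order = 60)
  stopifnot(length(elems) == 60)
  structure(list(order = 60L, rotations = elems, name = "I"),
            class = "symmetry_group")
}

#' Tetrahedral rotation group (order 12)
#'
#' @return A `symmetry_group` of order 12 (identity first).
#' @export
tetrahedral_group <- function() {
  # tetrahedron vertices at alternating cube corners
  v1 <- c(1, 1, 1) / sqrt(3); v2 <- c(1, -1, -1) / sqrt(3)
  g1 <- rotation_about(v1, 2 * pi / 3)
  g2 <- rotation_about(v2, 2 * pi / 3)
  elems <- .group_closure(list(g1, g2), max_order = 12)
  stopifnot(length(elems) == 12)
  structure(list(order = 12L, rotations = elems, name = "T"),
            class = "symmetry_group")
}

#' @export
print.symmetry_group <- function(x, ...) {
  cat("symmetry_group", x$name, "of order", x$order, "\n")
  invisible(x)
}

#' Verify the group axioms numerically
#'
#' Checks that every element is a proper rotation (R'R = I, det = +1) and
#' that the set is closed under multiplication within tolerance.
#'
#' @param group A `symmetry_group`.
#' @param tol Numerical tolerance.
#' @return TRUE (invisibly) or an error describing the violation.
#' @export
check_group <- function(group, tol = 1e-8) {
  rots <- group$rotations
  for (r in rots) {
    if (max(abs(crossprod(r) - diag(3))) > tol || abs(det(r) - 1) > tol) {
      stop("group element is not a proper rotation")
    }
  }
  flat <- t(vapply(rots, as.numeric, numeric(9)))   # q x 9
  for (a in rots) {
    prods <- t(vapply(rots, function(b) as.numeric(a %*% b), numeric(9)))
    for (k in seq_len(nrow(prods))) {
      dmin <- min(rowSums(sweep(flat, 2, prods[k, ])^2))
      if (sqrt(dmin) > tol) stop("group not closed under multiplication")
    }
  }
  invisible(TRUE)
}
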