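# Mode-shape metrics: quantify how much of a mode's (mass-weighted) energy
# lives in each canonical motion pattern of the ring / cage / tile
# taxonomy, and label modes by the dominant pattern.
#
# Scores are squared mass-weighted projections of the mode vector onto a
# small template basis per category, normalized by the mode's total
# mass-weighted energy; they are invariant to mode sign and scale, and for
# degenerate eigen-groups they are averaged over the group (which makes
# them invariant to arbitrary remixing within the degenerate subspace).

.w3 <- function(cg) rep(cg$beads$mass, each = 3)

# assemble a 3N-column template from per-bead displacement rows
.field <- function(n, sel, disp) {
  v <- numeric(3 * n)
  ix <- rep(3 * (sel - 1), each = 3) + rep(1:3, length(sel))
  v[ix] <- as.numeric(t(disp))
  v
}

# M-orthonormalize template columns, dropping null directions
.orthonormalize <- function(Tm, w3) {
  G <- crossprod(Tm, Tm * w3)
  eg <- eigen((G + t(G)) / 2, symmetric = TRUE)
  keep <- eg$values > 1e-10 * max(eg$values, 0) & eg$values > 0
  if (!any(keep)) return(NULL)
  Tm %*% (eg$vectors[, keep, drop = FALSE] %*%
            diag(1 / sqrt(eg$values[keep]), sum(keep)))
}

# ring category templates
.ring_templates <- function(cg) {
  b <- cg$beads; n <- nrow(b)
  th <- atan2(b$y, b$x)
  inner <- which(b$role == "inner_circle")
  outer <- which(b$role %in% c("outer_circle", "single_stranded"))
  bridge <- which(b$role == "bridge")
  if (!length(inner) || !length(outer)) {
    abort_dnanma("ring scoring needs inner_circle/outer_circle role annotations",
                 "dnanma_unsupported_structure")
  }
  q <- max(b$copy)
  zf <- function(sel, amp) .field(n, sel, cbind(0, 0, amp))
  tmpl <- list(
    O_T = cbind(zf(inner, rep(1, length(inner)))),
    O_R = cbind(zf(inner, cos(th[inner])), zf(inner, sin(th[inner]))),
    I_T = cbind(.field(n, inner, cbind(1, 0, 0)), .field(n, inner, cbind(0, 1, 0))),
    zigzag = do.call(cbind, unlist(lapply(2:q, function(k) {
      list(zf(outer, cos(k * th[outer])), zf(outer, sin(k * th[outer])))
    }), recursive = FALSE)),
    spiderlike = cbind(zf(bridge, rep(1, length(bridge)))),
    # k = q would alias the uniform (spiderlike) pattern at the q discrete
    # bridge positions, so modulated bridge bending stops at q - 1
    mixed_spiderlike = do.call(cbind, unlist(lapply(seq_len(q - 1), function(k) {
      list(zf(bridge, cos(k * th[bridge])), zf(bridge, sin(k * th[bridge])))
    }), recursive = FALSE))
  )
  w3 <- .w3(cg)
  tmpl <- lapply(tmpl, .orthonormalize, w3 = w3)
  tmpl[!vapply(tmpl, is.null, TRUE)]
}

# flat-tile category templates (bending / tweezer / sticky-end motions)
.tile_templates <- function(cg) {
  b <- cg$beads; n <- nrow(b)
  arms <- sort(unique(b$seg[b$role == "arm"]))
  if (!length(arms)) {
    abort_dnanma("tile scoring needs arm segment annotations",
                 "dnanma_unsupported_structure")
  }
  w3 <- .w3(cg)
  bend <- twee <- sbend <- stwist <- list()
  for (a in arms) {
    # bending/tweezer live on the duplex arm body, the sticky categories on
    # the overhang beads, so the categories stay disjoint: a whole-arm flap
    # scores as bending, a tip-localized motion as a sticky-end mode
    s_ax <- which(b$seg == a & !b$sticky)
    s_st <- which(b$seg == a & b$sticky)
    xy <- cbind(b$x[s_ax], b$y[s_ax])
    s <- sqrt(rowSums(xy^2))
    # linear (pivot about the hub) and quadratic (cantilever flex) profiles
    p1 <- s / max(s); p2 <- p1^2
    d_a <- .unit(c(colMeans(xy), 0))
    tau <- c(-d_a[2], d_a[1], 0)
    bend[[a]] <- cbind(.field(n, s_ax, cbind(0, 0, p1)),
                       .field(n, s_ax, cbind(0, 0, p2)))
    twee[[a]] <- cbind(.field(n, s_ax, cbind(tau[1] * p1, tau[2] * p1, 0)),
                       .field(n, s_ax, cbind(tau[1] * p2, tau[2] * p2, 0)))
    if (length(s_st)) {
      sbend[[a]] <- .field(n, s_st, cbind(0, 0, rep(1, length(s_st))))
      # twisting about the arm axis: rotation field of the off-axis offsets
      ps <- cbind(b$x[s_st], b$y[s_st], b$z[s_st])
      along <- ps %*% d_a
      off <- ps - along %*% t(d_a)
      rot <- t(apply(off, 1, function(o) c(d_a[2] * o[3] - d_a[3] * o[2],
                                           d_a[3] * o[1] - d_a[1] * o[3],
                                           d_a[1] * o[2] - d_a[2] * o[1])))
      stwist[[a]] <- .field(n, s_st, rot)
    }
  }
  tmpl <- list(
    bending = do.call(cbind, bend),
    tweezer = do.call(cbind, twee),
    sticky_bend = do.call(cbind, sbend),
    sticky_twist = do.call(cbind, stwist)
  )
  tmpl <- lapply(tmpl, function(x) if (is.null(x)) NULL else .orthonormalize(x, w3))
  tmpl[!vapply(tmpl, is.null, TRUE)]
}

.score_templates <- function(v, tmpl, w3) {
  vv <- sum(v^2 * w3)
  vapply(tmpl, function(B) sum(crossprod(B, w3 * v)^2) / vv, 0)
}

#' Ring-motion scores of a mode vector
#'
#' Scores the mode against the ring taxonomy: out-of-plane translation
#' (O_T) and rotation (O_R, the seesaw) of the inner circle, in-plane
#' translation (I_T), outer-circle zigzag (sinusoidal z-undulation at
#' angular wavenumber >= 2), and coherent (spiderlike) or modulated
#' (mixed spiderlike) out-of-plane bridge bending.
#'
#' @param v Mode vector (3N) or a matrix of vectors (columns).
#' @param cg The ring [cg_model()] (roles inner_circle / outer_circle /
#'   bridge required).
#' @return Named score vector in [0, 1] (averaged over columns if a matrix).
#' @export
ring_mode_scores <- function(v, cg) {
  tmpl <- .ring_templates(cg)
  w3 <- .w3(cg)
  v <- as.matrix(v)
  rowMeans(apply(v, 2, .score_templates, tmpl = tmpl, w3 = w3))
}

#' Cage-motion scores of a mode vector
#'
#' Scores against the cage taxonomy: overall breathing (O_B, coherent
#' radial motion of the whole cage), local breathing (L_B, radial energy
#' that is spatially concentrated, the "spiky" pattern), and torsional
#' motion (twisting of arms about their own axes).
#'
#' @inheritParams ring_mode_scores
#' @param cg The cage [cg_model()].
#' @return Named score vector with entries O_B, L_B, torsional.
#' @export
ball_mode_scores <- function(v, cg) {
  b <- cg$beads; n <- nrow(b)
  ctr <- colMeans(as.matrix(b[, c("x", "y", "z")]))
  P <- sweep(as.matrix(b[, c("x", "y", "z")]), 2, ctr)
  rr <- sqrt(rowSums(P^2))
  if (max(rr) < 1e-9 || stats::sd(rr) / max(rr) > 0.9) {
    abort_dnanma("degenerate centroid geometry", "dnanma_unsupported_structure")
  }
  rhat <- P / rr
  m <- b$mass
  # per-arm twisting fields depend only on the geometry: precompute
  armsel <- split(seq_len(n), paste(b$copy, b$seg))
  arms <- list()
  for (sel in armsel) {
    sel <- sel[b$role[sel] == "arm"]
    if (length(sel) < 6) next
    ps <- P[sel, , drop = FALSE]
    d_a <- .unit(ps[nrow(ps), ] - ps[1, ])
    along <- as.numeric(ps %*% d_a)
    off <- ps - along %*% t(d_a)
    rot <- cbind(d_a[2] * off[, 3] - d_a[3] * off[, 2],
                 d_a[3] * off[, 1] - d_a[1] * off[, 3],
                 d_a[1] * off[, 2] - d_a[2] * off[, 1])
    nrm <- sum(m[sel] * rowSums(rot^2))
    if (nrm < 1e-12) next
    arms[[length(arms) + 1]] <- list(sel = sel, rot = rot, nrm = nrm)
  }
  v <- as.matrix(v)
  one <- function(vk) {
    D <- matrix(vk, 3)                      # 3 x N displacements
    vv <- sum(m * colSums(D^2))
    drad <- colSums(t(rhat) * D)
    ob <- sum(m * drad)^2 / (sum(m) * vv)
    erad <- m * drad^2
    f_rad <- sum(erad) / vv
    pr <- sum(erad)^2 / (n * sum(erad^2))
    lb <- max(0, f_rad - ob) * (1 - pr)
    tor_num <- 0
    for (ar in arms) {
      pj <- sum(m[ar$sel] * rowSums(ar$rot * t(D[, ar$sel, drop = FALSE])))
      tor_num <- tor_num + pj^2 / ar$nrm
    }
    c(O_B = ob, L_B = lb, torsional = tor_num / vv)
  }
  rowMeans(apply(v, 2, one))
}

#' Three-point-star tile motion scores
#'
#' Scores against the flat-tile taxonomy: out-of-plane arm bending,
#' in-plane tweezer-like arm motion, and bending or twisting localized at
#' the sticky ends.
#'
#' @inheritParams ring_mode_scores
#' @param cg The flat 3PS tile [cg_model()] (arm/sticky annotations).
#' @return Named score vector.
#' @export
tile_mode_scores <- function(v, cg) {
  tmpl <- .tile_templates(cg)
  w3 <- .w3(cg)
  v <- as.matrix(v)
  rowMeans(apply(v, 2, .score_templates, tmpl = tmpl, w3 = w3))
}

#' Label the non-rigid modes of a mode set
#'
#' Applies the structure-appropriate scorer to every non-rigid mode,
#' grouping numerically degenerate eigenvalues and scoring them jointly on
#' their invariant subspace.  A mode whose top two scores differ by less
#' than the mixed margin is labeled "mixed".
#'
#' @param modes A `mode_set`.
#' @param cg The matching [cg_model()].
#' @param structure "ring", "buckyball" or "tile".
#' @param n_label Number of non-rigid modes to label (default 10).
#' @param margin Mixed-label margin (default 0.15).
#' @param degeneracy_tol Relative eigenvalue gap under which consecutive
#'   modes are treated as one degenerate group.
#' @return The `mode_set` with `labels` and a `scores` matrix attached
#'   (row per labeled mode; mode numbering starts after the rigid modes).
#' @export
label_modes <- function(modes, cg, structure = c("ring", "buckyball", "tile"),
                        n_label = 10, margin = dnanma_defaults()$mixed_margin,
                        degeneracy_tol = 1e-4) {
  structure_ <- match.arg(structure)
  scorer <- switch(structure_, ring = ring_mode_scores,
                   buckyball = ball_mode_scores, tile = tile_mode_scores)
  z <- modes$zero_modes
  idx <- seq(z + 1, min(z + n_label, length(modes$lambda)))
  lam <- modes$lambda[idx]
  grp <- cumsum(c(1, diff(lam) > degeneracy_tol * pmax(abs(lam[-1]), 1e-300)))
  labels <- character(length(idx))
  scores <- NULL
  for (g in unique(grp)) {
    sel <- idx[grp == g]
    sc <- scorer(modes$vectors[, sel, drop = FALSE], cg)
    top <- sort(sc, decreasing = TRUE)
    lab <- if (length(top) >= 2 && (top[1] - top[2]) < margin) "mixed" else names(top)[1]
    labels[grp == g] <- lab
    scores <- rbind(scores, matrix(rep(sc, sum(grp == g)), nrow = sum(grp == g),
                                   byrow = TRUE, dimnames = list(NULL, names(sc))))
  }
  modes$labels <- labels
  modes$scores <- scores
  modes$label_structure <- structure_
  modes
}

#' Synthetic pure-category displacement field
#'
#' Constructs an idealized displacement field that belongs purely to one
#' taxonomy category; used by the property tests of the classifier.
#'
#' @param cg A [cg_model()].
#' @param structure "ring", "buckyball" or "tile".
#' @param category Category name as returned by the matching scorer.
#' @return A 3N displacement vector.
#' @export
synthetic_mode_field <- function(cg, structure = c("ring", "buckyball", "tile"),
                                 category) {
  structure_ <- match.arg(structure)
  n <- nrow(cg$beads)
  if (structure_ == "ring") {
    tmpl <- .ring_templates(cg)
    return(as.numeric(tmpl[[category]][, 1]))
  }
  if (structure_ == "tile") {
    tmpl <- .tile_templates(cg)
    return(as.numeric(tmpl[[category]][, 1]))
  }
  b <- cg$beads
  ctr <- colMeans(as.matrix(b[, c("x", "y", "z")]))
  P <- sweep(as.matrix(b[, c("x", "y", "z")]), 2, ctr)
  rhat <- P / sqrt(rowSums(P^2))
  if (category == "O_B") return(as.numeric(t(rhat)))
  if (category == "L_B") {
    v <- matrix(0, n, 3)
    sel <- which(b$copy == 1)
    sel <- sel[seq_len(max(1, length(sel) %/% 20))]
    v[sel, ] <- rhat[sel, ]
    return(as.numeric(t(v)))
  }
  if (category == "torsional") {
    v <- matrix(0, n, 3)
    for (a in unique(paste(b$copy, b$seg))) {
      sel <- which(paste(b$copy, b$seg) == a & b$role == "arm")
      if (length(sel) < 6) next
      ps <- P[sel, , drop = FALSE]
      d_a <- .unit(ps[nrow(ps), ] - ps[1, ])
      along <- as.numeric(ps %*% d_a)
      off <- ps - along %*% t(d_a)
      v[sel, ] <- cbind(d_a[2] * off[, 3] - d_a[3] * off[, 2],
                        d_a[3] * off[, 1] - d_a[1] * off[, 3],
                        d_a[1] * off[, 2] - d_a[2] * off[, 1])
    }
    return(as.numeric(t(v)))
  }
  abort_dnanma(paste("unknown category", category), "dnanma_invalid_input")
}
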