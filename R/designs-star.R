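# Three-point-star (3PS) tile designs and the cage assemblies built from
# them: the 60-tile buckyball (icosahedral rotation group on a truncated
# icosahedron) and a 12-tile tetrahedral mini-ball fixture (same builder on
# a truncated tetrahedron).
#
# Cage geometry: tile centers are the orbit of one truncated-polyhedron
# vertex under the rotation group (the group acts simply transitively on
# the 60 resp. 12 vertices).  Every tile-graph edge carries one continuous
# duplex along the chord between neighboring tile centers; its two halves
# belong to the two tiles and the central `sticky_len` base pairs are the
# hybridized sticky ends (strand A owned by one tile, strand B by the
# other).  Edge duplexes are built exactly dyad-symmetric about the radial
# axis through the edge midpoint (palindromic sequence, twist phase zero at
# the midpoint), which is what makes copy i exactly equal to rotation i
# applied to copy 1.

#' Three-point-star tile / cage design
#'
#' @param kind "buckyball" (60 tiles, icosahedral), "mini_ball" (12 tiles,
#'   tetrahedral; a desk-scale fixture) or "tile" (single flat tile).
#' @param arm_bp Duplex base pairs per arm half-edge (default 13).
#' @param sticky_len Sticky-end overhang length in nt (default 6, must be
#'   even so edge duplexes stay dyad-symmetric).
#' @param loop_nt Nucleotides per single-stranded central T-loop (default 4).
#' @param d0 Clearance between a tile center and its arm inner ends, nm.
#' @param include_5p Keep 5'-terminal phosphates.
#' @return Object of class `star_design`.
#' @export
star_design <- function(kind = c("buckyball", "mini_ball", "tile"),
                        arm_bp = NULL, sticky_len = 2, loop_nt = 4,
                        bundle = 1, bundle_sep = 2.4, d0 = NULL,
                        include_5p = FALSE) {
  kind <- match.arg(kind)
  p <- dnanma_defaults()
  if (is.null(d0)) {
    d0 <- if (bundle >= 2) 2.8 else if (kind == "mini_ball") 2.4 else 1.2
  }
  # the default arm length puts the assembled cage at the ~80 nm diameter
  # of the design scheme (edge chord 15 nm, circumradius 37 nm)
  if (is.null(arm_bp)) arm_bp <- if (kind == "mini_ball") 4L else 18L
  stopifnot(arm_bp >= 2, sticky_len >= 2, sticky_len %% 2 == 0, loop_nt >= 1,
            bundle %in% c(1L, 2L))
  n_edge <- 2L * arm_bp + sticky_len
  structure(list(
    kind = kind, arm_bp = as.integer(arm_bp), sticky_len = as.integer(sticky_len),
    loop_nt = as.integer(loop_nt), d0 = d0,
    bundle = as.integer(bundle), bundle_sep = bundle_sep,
    n_edge = as.integer(n_edge),
    edge_len = (n_edge - 1) * p$rise + 2 * d0,
    rise = p$rise, twist = p$twist,
    include_5p = include_5p
  ), class = c("star_design", "tile_design"))
}

#' @export
print.star_design <- function(x, ...) {
  cat(sprintf("star_design (%s): arms %d bp + %d nt sticky, %d nt T-loops\n",
              x$kind, x$arm_bp, x$sticky_len, x$loop_nt))
  cat(sprintf("  edge duplex %d bp, tile spacing %.2f nm\n", x$n_edge, x$edge_len))
  invisible(x)
}

#' @export
design_segments.star_design <- function(design) {
  hel <- if (design$bundle == 2L) c("a", "b") else ""
  arms <- as.vector(outer(paste0("arm", 1:3), hel, paste0))
  data.frame(
    seg = c(arms, paste0("loop", 1:3)),
    role = c(rep("arm", length(arms)), rep("loop", 3)),
    bp = c(rep(design$arm_bp + design$sticky_len, length(arms)),
           rep(design$loop_nt, 3)),
    stringsAsFactors = FALSE
  )
}

# base polyhedron vertices (unit circumradius) and matching rotation group
.poly_geometry <- function(kind) {
  if (kind == "buckyball") {
    list(verts = .icosahedron_vertices(), group = icosahedral_group(), k_vertex = 5L)
  } else {
    v <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)
    list(verts = v, group = tetrahedral_group(), k_vertex = 3L)
  }
}

# tile-1 placement: its center u, its hexagon-edge partner, its "CCW"
# pentagon/triangle neighbor, and the vertex rotation rho mapping tile 1
# onto that neighbor
.star_geometry <- function(design) {
  pg <- .poly_geometry(design$kind)
  V <- pg$verts
  D <- as.matrix(stats::dist(V))
  a_u <- min(D[D > 1e-9])
  nbr <- function(i) which(abs(D[i, ] - a_u) < 1e-6)
  f <- design$edge_len / (a_u / 3)
  Vs <- V * f
  A_i <- 1L; B_i <- min(nbr(A_i))
  A <- Vs[A_i, ]; B <- Vs[B_i, ]
  u <- A + (B - A) / 3
  w_hex <- B + (A - B) / 3
  common <- intersect(nbr(A_i), nbr(B_i))
  rho <- NULL; p_ccw <- NULL
  for (C_i in common) for (sgn in c(1, -1)) {
    r <- rotation_about(A, sgn * 2 * pi / pg$k_vertex)
    tgt <- Vs[A_i, ] + (Vs[C_i, ] - Vs[A_i, ]) / 3
    if (sqrt(sum((as.numeric(r %*% u) - tgt)^2)) < 1e-6 * f) {
      rho <- r; p_ccw <- tgt
    }
  }
  stopifnot(!is.null(rho))
  list(u = u, w_hex = w_hex, p_ccw = p_ccw, rho = rho,
       group = pg$group, verts = Vs, k_vertex = pg$k_vertex)
}

# one full edge duplex between tile centers u and v (optionally displaced
# by `offset`), with tile ownership in the copy column (1 = u's half,
# 2 = v's half)
.build_edge <- function(u, v, design, seg, nt_start, offset = c(0, 0, 0)) {
  n <- design$n_edge; arm <- design$arm_bp; stk <- design$sticky_len
  m <- (u + v) / 2 + offset
  axis <- .unit(v - u)
  y0 <- .unit((u + v) / 2)   # radial dyad axis, orthogonal to the chord
  k <- seq_len(n)
  own_a <- ifelse(k <= arm + stk, 1L, 2L)
  own_b <- ifelse(k <= arm, 1L, 2L)
  sticky <- k > arm & k <= arm + stk
  eng <- list(type = "straight", origin = m, axis = axis, y0 = y0,
              rise = design$rise, twist = design$twist, s0 = -(n - 1) / 2)
  .place_segment(
    n, .palindromic_seq(n), eng,
    strand_a = sprintf("%s.A%d", seg, own_a),
    strand_b = sprintf("%s.B%d", seg, own_b),
    role_a = "arm",
    sticky_a = sticky, sticky_b = sticky,
    copy_a = own_a, copy_b = own_b,
    ord_a = ifelse(own_a == 1L, k, k - (arm + stk)),
    ord_b = ifelse(own_b == 1L, arm + 1L - k, n + 1L - k),
    seg = seg, nt_start = nt_start
  )
}

# An edge of the tile graph as a one- or two-helix bundle.  The second
# helix is built from the (v, u) direction at the mirrored transverse
# offset, which makes the pair exactly symmetric under the 2-fold rotation
# about the radial axis through the edge midpoint (the two helices swap);
# its ownership labels are swapped so copy 1 is always u's half.
# Returns a list of segment bundles and the inner-end bp index per segment.
.build_edge_bundle <- function(u, v, design, segbase, nt_start) {
  if (design$bundle == 1L) {
    sg <- .build_edge(u, v, design, segbase, nt_start)
    return(list(segs = list(sg), inner_bp = stats::setNames(1L, segbase),
                nt_next = sg$nt_next))
  }
  tvec <- .unit(v - u); rm <- .unit((u + v) / 2)
  bv <- c(tvec[2] * rm[3] - tvec[3] * rm[2],
          tvec[3] * rm[1] - tvec[1] * rm[3],
          tvec[1] * rm[2] - tvec[2] * rm[1])
  h <- design$bundle_sep / 2
  e_a <- .build_edge(u, v, design, paste0(segbase, "a"), nt_start, offset = h * bv)
  e_b <- .build_edge(v, u, design, paste0(segbase, "b"), e_a$nt_next, offset = -h * bv)
  e_b$atoms$copy <- 3L - e_b$atoms$copy
  list(segs = list(e_a, e_b),
       inner_bp = stats::setNames(c(1L, design$n_edge),
                                  paste0(segbase, c("a", "b"))),
       nt_next = e_b$nt_next)
}

# double-crossover anchors between the two helices of each bundle arm:
# the helices are linked near both ends of the arm (10% and 90% of the
# radial span from the tile center), like the crossovers of a DX motif
.bundle_links <- function(atoms, center) {
  g <- atoms[atoms$glyc & atoms$role == "arm" & atoms$copy == 1L, , drop = FALSE]
  if (!nrow(g)) return(data.frame(nt_a = integer(), nt_b = integer()))
  arm_id <- sub("^(arm[0-9]+).*$", "\\1", g$seg)
  hel <- sub("^arm[0-9]+", "", g$seg)
  if (!any(hel == "b")) return(data.frame(nt_a = integer(), nt_b = integer()))
  la <- lb <- integer(0)
  dctr <- sqrt((g$x - center[1])^2 + (g$y - center[2])^2 + (g$z - center[3])^2)
  for (a in unique(arm_id)) {
    ga <- which(arm_id == a & hel == "a"); gb <- which(arm_id == a & hel == "b")
    if (!length(ga) || !length(gb)) next
    for (q in c(0.1, 0.9)) {
      d_star <- min(dctr[ga]) + q * (max(dctr[ga]) - min(dctr[ga]))
      i <- ga[which.min(abs(dctr[ga] - d_star))]
      d2 <- (g$x[gb] - g$x[i])^2 + (g$y[gb] - g$y[i])^2 + (g$z[gb] - g$z[i])^2
      j <- gb[which.min(d2)]
      la <- c(la, g$nt[i]); lb <- c(lb, g$nt[j])
    }
  }
  unique(data.frame(nt_a = la, nt_b = lb))
}

# Single-stranded loop of loop_nt thymines between two strand-terminus
# points.  The nucleotide template is re-centered on its C1' and compressed
# toward the loop path: a single strand has no helix cross-section, and the
# three loops of a tile pass close enough to each other that full-width
# templates would interpenetrate.
.build_loop <- function(p1, p2, normal, design, seg, nt_start,
                        compress = 0.3) {
  off <- 0.35
  e1 <- p1 + off * normal; e2 <- p2 + off * normal
  axis <- .unit(e2 - e1)
  y0 <- normal - sum(normal * axis) * axis
  if (sqrt(sum(y0^2)) < 1e-6) y0 <- c(axis[2], -axis[1], 0)
  y0 <- .unit(y0)
  rise <- sqrt(sum((e2 - e1)^2)) / (design$loop_nt + 1)
  eng <- list(type = "straight", origin = e1, axis = axis, y0 = y0,
              rise = rise, twist = 0, s0 = 1)
  sg <- .place_segment(
    design$loop_nt, rep("T", design$loop_nt), eng,
    present_b = rep(FALSE, design$loop_nt),
    strand_a = paste0(seg, ".A"), role_a = "loop",
    copy_a = 1L, ord_a = seq_len(design$loop_nt),
    seg = seg, nt_start = nt_start
  )
  a <- sg$atoms
  for (k in unique(a$bp)) {
    sel <- a$bp == k
    ctr <- e1 + axis * rise * k
    for (cc in c("x", "y", "z")) {
      a[[cc]][sel] <- ctr[match(cc, c("x", "y", "z"))] +
        compress * (a[[cc]][sel] - ctr[match(cc, c("x", "y", "z"))])
    }
  }
  sg$atoms <- a
  sg
}

# C1' position of the terminal nucleotide of one strand at a tile-center
# arm end ("A" or "B" side); used as the loop attachment point
.arm_attach <- function(atoms, seg_name, side, inner_bp) {
  s <- atoms[atoms$seg == seg_name & atoms$bp == inner_bp &
               atoms$name == "C1'" & grepl(paste0("\\.", side), atoms$strand), ,
             drop = FALSE]
  list(p = as.numeric(s[1, c("x", "y", "z")]), nt = s$nt[1])
}

# build the three T-loops between arm strand termini, choosing the
# non-crossing matching: the six attachment points are ordered by azimuth
# around the tile normal and adjacent points of different arms are joined
.tile_loops <- function(atoms, center, normal, design, inner_bp, nt0) {
  pts <- list()
  for (sg in names(inner_bp)) for (side in c("A", "B")) {
    at <- .arm_attach(atoms, sg, side, inner_bp[[sg]])
    pts[[length(pts) + 1]] <- list(arm = sub("^(arm[0-9]+).*$", "\\1", sg),
                                   p = at$p, nt = at$nt)
  }
  e1 <- c(1, 0, 0); if (abs(sum(e1 * normal)) > 0.9) e1 <- c(0, 1, 0)
  e1 <- .unit(e1 - sum(e1 * normal) * normal)
  e2 <- c(normal[2] * e1[3] - normal[3] * e1[2],
          normal[3] * e1[1] - normal[1] * e1[3],
          normal[1] * e1[2] - normal[2] * e1[1])
  ang <- vapply(pts, function(q) atan2(sum((q$p - center) * e2),
                                       sum((q$p - center) * e1)), 0)
  ordn <- order(ang)
  loops <- list(); li <- 0
  hub_a <- hub_b <- integer(0)
  for (k in seq_along(ordn)) {
    a1 <- pts[[ordn[k]]]; a2 <- pts[[ordn[k %% length(ordn) + 1]]]
    if (a1$arm == a2$arm) next
    li <- li + 1
    loops[[li]] <- .build_loop(a1$p, a2$p, normal, design,
                               paste0("loop", li), nt0)
    nt0 <- loops[[li]]$nt_next
    # direct crossover between the adjacent arm termini: the central strand
    # of a three-point-star tile passes straight through the junction, so
    # the hub is held by strand crossovers, not by the T-loops alone
    hub_a <- c(hub_a, a1$nt); hub_b <- c(hub_b, a2$nt)
  }
  list(loops = loops, hub_links = data.frame(nt_a = hub_a, nt_b = hub_b))
}

# Link loop terminal nucleotides to the two nearest arm nucleotides (the
# termini of both strands at the arm end).  Anchoring each loop end on both
# sides of the duplex end leaves no free rotation of an edge duplex about
# its own axis, which a single axial attachment per end would allow.
.loop_links <- function(atoms) {
  a <- data.table::as.data.table(atoms)
  ref <- a[glyc == TRUE, .(nt, x, y, z, role, ord, strand, copy)]
  arms <- ref[role == "arm"]
  loops <- ref[role == "loop"]
  if (!nrow(loops)) return(data.frame(nt_a = integer(), nt_b = integer()))
  ends <- loops[, .SD[ord == min(ord) | ord == max(ord)], by = strand]
  link_a <- link_b <- integer(0)
  for (i in seq_len(nrow(ends))) {
    e <- ends[i]
    tgt <- arms[copy == e$copy]
    d2 <- (tgt$x - e$x)^2 + (tgt$y - e$y)^2 + (tgt$z - e$z)^2
    near2 <- tgt$nt[order(d2)[1:2]]
    link_a <- c(link_a, e$nt, e$nt); link_b <- c(link_b, near2)
  }
  data.frame(nt_a = link_a, nt_b = link_b)
}

#' @describeIn build_tile Curved 3PS tile positioned at its cage vertex
#'   (`flat = FALSE`), or the flat reference tile in the xy-plane used for
#'   unit-tile mode analysis (`flat = TRUE`).
#' @param flat Build the flat xy-plane tile instead of the cage-vertex tile.
#' @export
build_tile.star_design <- function(design, flat = (design$kind == "tile"), ...) {
  if (flat) return(.build_flat_tile(design))
  geom <- .star_geometry(design)
  n <- design$n_edge
  hexb <- .build_edge_bundle(geom$u, geom$w_hex, design, "arm1", nt_start = 1L)
  pentb <- .build_edge_bundle(geom$u, geom$p_ccw, design, "arm2", hexb$nt_next)
  keep_pairs <- function(sg, nts) sg$pairs[sg$pairs$nt_a %in% nts & sg$pairs$nt_b %in% nts, ]
  atoms_l <- list(); pairs_l <- list()
  inner_bp <- c(hexb$inner_bp, pentb$inner_bp)
  # near halves belong to tile 1 as built
  for (sg in c(hexb$segs, pentb$segs)) {
    near <- sg$atoms[sg$atoms$copy == 1L, ]
    atoms_l[[length(atoms_l) + 1]] <- near
    pairs_l[[length(pairs_l) + 1]] <- keep_pairs(sg, near$nt)
  }
  # the far halves of the pentagon edge, pulled back by rho^-1, are tile
  # 1's third arm (rho applied to them reproduces that edge's far halves)
  for (sg in pentb$segs) {
    far <- sg$atoms[sg$atoms$copy == 2L, ]
    pos <- as.matrix(far[, c("x", "y", "z")]) %*% geom$rho
    far$x <- pos[, 1]; far$y <- pos[, 2]; far$z <- pos[, 3]
    far$copy <- 1L
    segname3 <- sub("^arm2", "arm3", far$seg[1])
    # the far half's inner end sits at the opposite bp end from the near half
    inner_bp[segname3] <- if (inner_bp[[far$seg[1]]] == 1L) n else 1L
    far$seg <- segname3
    far$strand <- sub("^arm2", "arm3", far$strand)
    atoms_l[[length(atoms_l) + 1]] <- far
    pairs_l[[length(pairs_l) + 1]] <- keep_pairs(sg, far$nt)
  }
  atoms <- do.call(rbind, atoms_l)
  pairs <- do.call(rbind, pairs_l)
  # T-loops between arm strand termini at the tile center
  normal <- .unit(geom$u)
  lp <- .tile_loops(atoms, geom$u, normal, design, inner_bp = inner_bp,
                    nt0 = pentb$nt_next)
  atoms <- rbind(atoms, do.call(rbind, lapply(lp$loops, `[[`, "atoms")))
  atoms <- .drop_5p_phosphates(atoms, design$include_5p)
  links <- rbind(.loop_links(atoms), .bundle_links(atoms, geom$u))
  fine_model(atoms, pairs, links,
             meta = list(kind = "star_tile", design = design,
                         tile_center = geom$u, group_name = geom$group$name))
}

.build_flat_tile <- function(design) {
  arm <- design$arm_bp; stk <- design$sticky_len
  n <- arm + stk
  parts <- list(); nt0 <- 1L
  inner_bp <- integer(0)
  hels <- if (design$bundle == 2L) c("a", "b") else ""
  for (a in 1:3) {
    phi <- (90 + 120 * (a - 1)) * pi / 180
    d_a <- c(cos(phi), sin(phi), 0)
    b_a <- c(-d_a[2], d_a[1], 0)
    for (hi in seq_along(hels)) {
      off <- if (design$bundle == 2L) {
        (if (hels[hi] == "a") 1 else -1) * design$bundle_sep / 2 * b_a
      } else c(0, 0, 0)
      segname <- paste0("arm", a, hels[hi])
      eng <- list(type = "straight", origin = design$d0 * d_a + off, axis = d_a,
                  y0 = c(0, 0, 1), rise = design$rise, twist = design$twist, s0 = 0)
      k <- seq_len(n)
      sg <- .place_segment(
        n, .palindromic_seq(2 * arm + stk)[k], eng,
        present_b = k <= arm,
        strand_a = paste0(segname, ".A"), strand_b = paste0(segname, ".B"),
        role_a = "arm",
        sticky_a = k > arm, sticky_b = rep(FALSE, n),
        copy_a = 1L, ord_a = k, ord_b = arm + 1L - k,
        seg = segname, nt_start = nt0
      )
      nt0 <- sg$nt_next
      parts[[length(parts) + 1]] <- sg
      inner_bp[segname] <- 1L
    }
  }
  normal <- c(0, 0, 1)
  atoms0 <- do.call(rbind, lapply(parts, `[[`, "atoms"))
  lp <- .tile_loops(atoms0, c(0, 0, 0), normal, design,
                    inner_bp = inner_bp, nt0 = nt0)
  parts <- c(parts, lp$loops)
  atoms <- do.call(rbind, lapply(parts, `[[`, "atoms"))
  pairs <- do.call(rbind, lapply(parts, `[[`, "pairs"))
  atoms <- .drop_5p_phosphates(atoms, design$include_5p)
  links <- rbind(.loop_links(atoms), .bundle_links(atoms, c(0, 0, 0)))
  fine_model(atoms, pairs, links,
             meta = list(kind = "tile3ps_flat", design = design))
}

#' Build a flat three-point-star tile
#'
#' Convenience wrapper: the planar 3PS reference tile (three duplex arms at
#' 120 degrees with sticky overhangs and central T-loops) used for
#' unit-tile normal mode analysis.
#'
#' @param design A [star_design()] (defaults to the buckyball tile design).
#' @return A [fine_model()].
#' @export
build_3ps_tile <- function(design = star_design()) {
  build_tile.star_design(design, flat = TRUE)
}

#' Build the 60-tile buckyball cage
#'
#' @param design A [star_design()] with kind "buckyball".
#' @return A [fine_model()] of the assembled cage.
#' @export
build_buckyball <- function(design = star_design("buckyball")) {
  geom <- .star_geometry(design)
  assemble(build_tile(design, flat = FALSE), geom$group)
}

#' Build the tetrahedral 12-tile mini-ball fixture
#'
#' @param design A [star_design()] with kind "mini_ball".
#' @return A [fine_model()].
#' @export
build_mini_ball <- function(design = star_design("mini_ball", loop_nt = 5)) {
  geom <- .star_geometry(design)
  assemble(build_tile(design, flat = FALSE), geom$group)
}
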