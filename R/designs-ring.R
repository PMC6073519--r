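# Parameterized designs and builders for the 2D ring assemblies.
#
# A ring is 12 congruent tiles: an inner-circle arc duplex, an outer-circle
# arc duplex, and radial bridge duplexes, with 6-nt sticky-end nicks in both
# arcs at every tile boundary.  Open-form variants additionally carry an
# 8-nt single-stranded domain in the outer circle.  Both arcs are built as
# circular arcs (the duplex axis follows the circle), with the twist per
# tile quantized to whole helical turns so the assembly is exactly
# 12-fold symmetric.

#' Ring tile design
#'
#' Creates the declarative description of one of the four ring designs.
#' Per-segment base-pair counts default to values derived from the target
#' diameters under canonical B-form geometry (0.34 nm rise): the inner
#' diameter fixes the inner-circle arc length directly, while the outer
#' diameter is measured over atoms and therefore has the maximum atom
#' radius of the duplex template subtracted before conversion to base pairs.
#'
#' @param variant "r1o", "r1c", "r2o" or "r2c" (open/closed R1 and R2).
#' @param n_tiles Number of tiles (default 12).
#' @param outer_diameter,inner_diameter Target diameters in nm.  Defaults:
#'   29/13 for R1, 55/40 for R2.
#' @param inner_bp,outer_bp Base pairs per tile on each arc; derived from
#'   the diameters when NULL.
#' @param bridge_bp Base pairs per radial bridge; derived from the radial
#'   gap when NULL.
#' @param bridges_per_tile 1 for R1 tiles; 2 for the composite R2 tile
#'   (unit tile plus connection tile).
#' @param sticky_len Sticky-end overhang length in nt (default 6).
#' @param ss_len Length of the single-stranded domain (8 for open variants,
#'   0 for closed).
#' @param include_5p Keep 5'-terminal phosphates (default FALSE, the
#'   synthesis convention).
#' @return Object of class `ring_design`.
#' @export
ring_design <- function(variant = c("r1o", "r1c", "r2o", "r2c"),
                        n_tiles = 12,
                        outer_diameter = NULL, inner_diameter = NULL,
                        inner_bp = NULL, outer_bp = NULL, bridge_bp = NULL,
                        bridges_per_tile = NULL,
                        sticky_len = 6, ss_len = NULL,
                        bridge_clear = NULL, junction_xlink_bp = 2,
                        junction_links_per_end = 1,
                        include_5p = FALSE) {
  variant <- match.arg(variant)
  p <- dnanma_defaults()
  is_r2 <- variant %in% c("r2o", "r2c")
  if (is.null(outer_diameter)) outer_diameter <- if (is_r2) 55 else 29
  if (is.null(inner_diameter)) inner_diameter <- if (is_r2) 40 else 13
  if (is.null(ss_len)) ss_len <- if (variant %in% c("r1o", "r2o")) 8 else 0
  if (is.null(bridges_per_tile)) bridges_per_tile <- if (is_r2) 2 else 1
  r_atom <- 1.04   # maximum atom radius of the duplex template (OP1)
  if (is.null(inner_bp)) {
    inner_bp <- round(pi * inner_diameter / (n_tiles * p$rise))
  }
  if (is.null(outer_bp)) {
    outer_bp <- round(2 * pi * (outer_diameter / 2 - r_atom) / (n_tiles * p$rise))
  }
  R_in <- n_tiles * inner_bp * p$rise / (2 * pi)
  R_out <- n_tiles * outer_bp * p$rise / (2 * pi)
  # radial clearance between an arc axis and the nearest bridge bp center:
  # close enough that van der Waals springs couple the junction (a bridge
  # held by its covalent links alone could twist freely about its own axis)
  # but outside the clash distance of the arc's atoms
  if (is.null(bridge_clear)) bridge_clear <- r_atom + p$clash_dist + 0.01
  if (is.null(bridge_bp)) {
    gap <- R_out - R_in
    bridge_bp <- floor((gap - 2 * bridge_clear) / p$rise)
  }
  stopifnot(sticky_len + ss_len < outer_bp, sticky_len < inner_bp, bridge_bp >= 2)
  # whole helical turns per tile so the ring closes with exact C12 symmetry
  turns_in <- max(1, round(inner_bp * p$twist / 360))
  turns_out <- max(1, round(outer_bp * p$twist / 360))
  structure(list(
    variant = variant, n_tiles = as.integer(n_tiles),
    outer_diameter = outer_diameter, inner_diameter = inner_diameter,
    inner_bp = as.integer(inner_bp), outer_bp = as.integer(outer_bp),
    bridge_bp = as.integer(bridge_bp),
    bridges_per_tile = as.integer(bridges_per_tile),
    sticky_len = as.integer(sticky_len), ss_len = as.integer(ss_len),
    ss_start = as.integer(sticky_len),   # ss domain starts right after the nick
    R_in = R_in, R_out = R_out, bridge_clear = bridge_clear,
    junction_xlink_bp = as.integer(junction_xlink_bp),
    junction_links_per_end = as.integer(junction_links_per_end),
    twist_in = turns_in * 360 / inner_bp, twist_out = turns_out * 360 / outer_bp,
    rise = p$rise, twist_bridge = p$twist, r_atom = r_atom,
    include_5p = include_5p
  ), class = c("ring_design", "tile_design"))
}

#' @export
print.ring_design <- function(x, ...) {
  cat(sprintf("ring_design %s: %d tiles, inner %d bp + outer %d bp per tile,\n",
              toupper(x$variant), x$n_tiles, x$inner_bp, x$outer_bp))
  cat(sprintf("  %d bridge(s) of %d bp per tile, sticky %d nt, ss domain %d nt\n",
              x$bridges_per_tile, x$bridge_bp, x$sticky_len, x$ss_len))
  cat(sprintf("  arc radii %.2f / %.2f nm (targets: %g / %g nm diameter)\n",
              x$R_in, x$R_out, x$inner_diameter, x$outer_diameter))
  invisible(x)
}

#' Segment table of a tile design
#'
#' @param design A tile design.
#' @return data.frame of segments with roles and base-pair counts.
#' @export
design_segments <- function(design) UseMethod("design_segments")

#' @export
design_segments.ring_design <- function(design) {
  data.frame(
    seg = c("inner", "outer", paste0("bridge", seq_len(design$bridges_per_tile))),
    role = c("inner_circle", "outer_circle", rep("bridge", design$bridges_per_tile)),
    bp = c(design$inner_bp, design$outer_bp, rep(design$bridge_bp, design$bridges_per_tile)),
    stringsAsFactors = FALSE
  )
}

# strand-A sequence motif for one tile of an arc (periodic over the ring)
.arc_motif <- function(n) c("A", "C", "G", "T")[(seq_len(n) - 1) %% 4 + 1]

# drop 5'-terminal phosphate groups (one per strand fragment); the terminal
# O5' becomes a hydroxyl and gains one hydrogen mass
.drop_5p_phosphates <- function(atoms, include_5p = FALSE) {
  if (include_5p) return(atoms)
  a <- data.table::as.data.table(atoms)
  ends <- a[, .(ord5 = min(ord)), by = strand]
  a <- merge(a, ends, by = "strand", sort = FALSE)
  drop <- a$ord == a$ord5 & a$name %in% c("P", "OP1", "OP2")
  a$mass[a$ord == a$ord5 & a$name == "O5'"] <-
    a$mass[a$ord == a$ord5 & a$name == "O5'"] + ATOMIC_MASS["H"]
  a <- a[!drop]
  a[, ord5 := NULL]
  as.data.frame(a)
}

# one full arc circle with sticky nicks and (optionally) an ss gap
.ring_arc <- function(design, which = c("inner", "outer"), nt_start) {
  which <- match.arg(which)
  q <- design$n_tiles
  n <- if (which == "inner") design$inner_bp else design$outer_bp
  R <- if (which == "inner") design$R_in else design$R_out
  tw <- if (which == "inner") design$twist_in else design$twist_out
  role <- if (which == "inner") "inner_circle" else "outer_circle"
  stk <- design$sticky_len
  N <- q * n
  g <- seq_len(N) - 1L                      # global bp index
  in_tile <- g %% n                         # position within the tile pattern
  seq_a <- .arc_motif(n)[in_tile + 1L]
  # strand fragments: A nicks at tile boundaries, B nicks offset by the
  # sticky length; fragment ids number the tile copies
  frag_a <- g %/% n + 1L
  frag_b <- ((g - stk) %% N) %/% n + 1L
  ord_b <- n - ((g - (frag_b - 1L) * n - stk) %% N)
  present_b <- rep(TRUE, N)
  role_a <- rep(role, N)
  if (which == "outer" && design$ss_len > 0) {
    in_gap <- in_tile >= design$ss_start & in_tile < design$ss_start + design$ss_len
    present_b[in_gap] <- FALSE
    role_a[in_gap] <- "single_stranded"
  }
  sticky <- in_tile < stk
  # fragment-local chain position for strand B (5'->3' runs clockwise)
  pos_b <- (g - ((frag_b - 1L) * n + stk)) %% N
  eng <- list(type = "arc", radius = R, theta0 = pi / N, dtheta = 2 * pi / N,
              rise = design$rise, twist = tw, psi0 = 0)
  .place_segment(
    N, seq_a, eng, present_b = present_b,
    strand_a = sprintf("%s.A%02d", which, frag_a),
    strand_b = sprintf("%s.B%02d", which, frag_b),
    role_a = role_a, role_b = rep(role, N),
    sticky_a = sticky, sticky_b = sticky,
    copy_a = frag_a, copy_b = frag_b,
    ord_a = g + 1L, ord_b = n - pos_b,
    seg = which, nt_start = nt_start
  )
}

# radial bridge duplexes, one set per tile copy
.ring_bridges <- function(design, nt_start) {
  q <- design$n_tiles
  sector <- 2 * pi / q
  offs <- if (design$bridges_per_tile == 1) 0.5 else c(0.3, 0.7)
  clear <- design$bridge_clear
  span <- (design$bridge_bp - 1) * design$rise
  r0 <- design$R_in + clear + (design$R_out - design$R_in - 2 * clear - span) / 2
  parts <- list()
  nt <- nt_start
  for (s in seq_len(q)) {
    for (b in seq_along(offs)) {
      phi <- (s - 1 + offs[b]) * sector
      er <- c(cos(phi), sin(phi), 0)
      eng <- list(type = "straight", origin = r0 * er, axis = er,
                  y0 = c(0, 0, 1), rise = design$rise,
                  twist = design$twist_bridge, s0 = 0)
      sg <- .place_segment(
        design$bridge_bp, .arc_motif(design$bridge_bp), eng,
        strand_a = sprintf("bridge%d.A%02d", b, s),
        strand_b = sprintf("bridge%d.B%02d", b, s),
        role_a = "bridge", copy_a = s,
        seg = sprintf("bridge%d", b), nt_start = nt
      )
      nt <- sg$nt_next
      parts[[length(parts) + 1]] <- sg
    }
  }
  list(atoms = do.call(rbind, lapply(parts, `[[`, "atoms")),
       pairs = do.call(rbind, lapply(parts, `[[`, "pairs")),
       nt_next = nt)
}

# Designed junction links: each bridge terminal nucleotide is linked to an
# arc nucleotide, crossing over like the two strands of a double-crossover
# junction.  The A-strand terminus reaches `junction_xlink_bp` base pairs
# ahead along the arc and the B-strand terminus the same number behind, so
# the two links form an X.  Crossed links keep the junction stiff against
# in-plane shear and bridge torsion while leaving it bending-soft out of
# plane -- the mechanical signature of a strand-crossover junction.
.junction_links <- function(atoms, design) {
  a <- data.table::as.data.table(atoms)
  ref <- a[glyc == TRUE, .(nt, x, y, z, role, ord, strand)]
  ref[, rad := sqrt(x^2 + y^2)]
  br <- ref[role == "bridge"]
  ends <- br[, .SD[ord == min(ord) | ord == max(ord)], by = strand]
  inner <- ref[role == "inner_circle"]
  outer <- ref[role %in% c("outer_circle", "single_stranded")]
  xbp <- design$junction_xlink_bp %||% 0L
  per_end <- design$junction_links_per_end %||% 1L
  link_a <- link_b <- integer(0)
  for (i in seq_len(nrow(ends))) {
    e <- ends[i]
    to_inner <- abs(e$rad - design$R_in) < abs(e$rad - design$R_out)
    tgt <- if (to_inner) inner else outer
    Rarc <- if (to_inner) design$R_in else design$R_out
    sgns <- if (per_end >= 2L) c(1, -1) else if (grepl("\\.A", e$strand)) 1 else -1
    for (sgn in sgns) {
      ang <- sgn * xbp * design$rise / Rarc
      px <- e$x * cos(ang) - e$y * sin(ang)
      py <- e$x * sin(ang) + e$y * cos(ang)
      d2 <- (tgt$x - px)^2 + (tgt$y - py)^2 + (tgt$z - e$z)^2
      link_a <- c(link_a, e$nt); link_b <- c(link_b, tgt$nt[which.min(d2)])
    }
  }
  unique(data.frame(nt_a = link_a, nt_b = link_b))
}

# full ring construction (exactly C_q symmetric); the tile builder extracts
# copy 1 from this and the assembly re-creates it by rotation
.ring_full <- function(design) {
  inner <- .ring_arc(design, "inner", nt_start = 1L)
  outer <- .ring_arc(design, "outer", nt_start = inner$nt_next)
  bridges <- .ring_bridges(design, nt_start = outer$nt_next)
  atoms <- rbind(inner$atoms, outer$atoms, bridges$atoms)
  atoms <- .drop_5p_phosphates(atoms, design$include_5p)
  links <- .junction_links(atoms, design)
  fine_model(
    atoms,
    pairs = rbind(inner$pairs, outer$pairs, bridges$pairs),
    links = links,
    meta = list(kind = "ring", design = design,
                group_name = sprintf("C%d", design$n_tiles))
  )
}
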