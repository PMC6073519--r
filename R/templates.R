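# Idealized B-form nucleotide templates.
#
# A base pair is laid out in a local "bp frame": helix axis along z, base
# plane at z = 0, the strand-A C1' atom at (-0.50, -0.28) nm.  Strand B is
# the image of strand A under the duplex dyad (a 180 degree rotation about
# the y axis), which makes every template base pair exactly twofold
# symmetric -- the property the assembly builders rely on to obtain exactly
# symmetric rings and cages.
#
# Bases are regular fused polygons (bond 0.139 nm) oriented so that the
# Watson-Crick edge sites of the two partners face each other 0.29 nm apart,
# and so that the glycosidic nitrogen falls next to its C1' anchor.  The
# templates are stylized: masses and connectivity are exact (united-atom
# hydrogens, standard residue compositions), coordinates are idealized.

# strand-A C1' position in the bp frame (nm)
.C1_POS <- c(-0.50, -0.28)
.GLYC_BOND <- 0.147
.GLYC_DIR_DEG <- 50      # direction of the C1'->N bond, toward the pair axis
.RING_BOND <- 0.139

# primary Watson-Crick site targets on the strand-A side (x, y):
# purine N1 and pyrimidine N3 sit on the pair axis 0.29 nm from their
# partner's primary site; the axis is offset toward the pyrimidine.
.PRIMARY_PU <- c(-0.0535, 0.013)
.PRIMARY_PY <- c(-0.2365, 0.013)

# Backbone atom placements for a strand-A nucleotide: cylindrical
# coordinates (radius nm, azimuth offset from the C1' azimuth in degrees,
# z offset from the base plane in nm) plus united hydrogen counts.
.BACKBONE <- data.frame(
  name = c("P", "OP1", "OP2", "O5'", "C5'", "C4'", "O4'", "C3'", "O3'", "C2'", "C1'"),
  element = c("P", "O", "O", "O", "C", "C", "O", "C", "O", "C", "C"),
  r    = c(0.90, 1.04, 0.85, 0.84, 0.80, 0.72, 0.61, 0.78, 0.80, 0.65, 0.5735),
  dphi = c(-34, -30, -45, -26, -18, -11, -6, -3, 0.3, 2, 0),
  z    = c(-0.22, -0.27, -0.29, -0.19, -0.14, -0.05, 0.05, 0.02, 0.11, 0.06, 0),
  nH   = c(0, 0, 1, 0, 2, 1, 0, 1, 0, 2, 1),
  stringsAsFactors = FALSE
)

.unit2 <- function(v) v / sqrt(sum(v^2))

# vertices of a regular n-gon: vertex k at angle beta + k*step from center
.ngon <- function(center, R, beta, step, k) {
  ang <- beta + k * step
  cbind(center[1] + R * cos(ang), center[2] + R * sin(ang))
}

# Find the hexagon orientation that puts the glycosidic vertex closest to
# its anchor; returns ring atom coordinates for one base type.
.base_ring <- function(base) {
  g <- .C1_POS + .GLYC_BOND * c(cos(.GLYC_DIR_DEG * pi / 180),
                                sin(.GLYC_DIR_DEG * pi / 180))
  R6 <- .RING_BOND
  best <- NULL
  for (s in c(1, -1)) {
    step <- s * pi / 3
    obj <- function(beta) {
      if (base %in% PURINES) {
        # hexagon vertices: N1(0) C2(1) N3(2) C4(3) C5(4) C6(5); N1 pinned
        c6 <- .PRIMARY_PU - R6 * c(cos(beta), sin(beta))
        hx <- .ngon(c6, R6, beta, step, 0:5)
        # pentagon fused on the C4-C5 edge, apex N9 is the glycosidic atom
        mE <- (hx[4, ] + hx[5, ]) / 2
        a5 <- .RING_BOND / (2 * tan(pi / 5))
        R5 <- .RING_BOND / (2 * sin(pi / 5))
        c5 <- mE + a5 * .unit2(mE - c6)
        a4 <- atan2(hx[4, 2] - c5[2], hx[4, 1] - c5[1])
        aC5 <- atan2(hx[5, 2] - c5[2], hx[5, 1] - c5[1])
        d <- aC5 - a4
        d <- atan2(sin(d), cos(d))   # signed step C4 -> C5 (+-72 deg)
        n9 <- c5 + R5 * c(cos(a4 - d), sin(a4 - d))
        sum((n9 - g)^2)
      } else {
        # hexagon vertices N1(0)..C6(5); N3 (index 2) pinned
        cc <- .PRIMARY_PY - R6 * c(cos(beta + 2 * step), sin(beta + 2 * step))
        n1 <- cc + R6 * c(cos(beta), sin(beta))
        sum((n1 - g)^2)
      }
    }
    op <- stats::optimize(obj, c(0, 2 * pi))
    # chirality: keep the solution whose "upper" exocyclic carrier (C6 for
    # purines, C4 for pyrimidines) lies on the +y side, so the Watson-Crick
    # edge atoms of both partners face each other instead of overlapping
    beta_try <- op$minimum
    if (base %in% PURINES) {
      c6c <- .PRIMARY_PU - R6 * c(cos(beta_try), sin(beta_try))
      up <- (c6c[2] + R6 * sin(beta_try + 5 * step)) >
            (c6c[2] + R6 * sin(beta_try + 1 * step))   # C6 above C2
    } else {
      cc <- .PRIMARY_PY - R6 * c(cos(beta_try + 2 * step), sin(beta_try + 2 * step))
      up <- (cc[2] + R6 * sin(beta_try + 3 * step)) >
            (cc[2] + R6 * sin(beta_try + 1 * step))    # C4 above C2
    }
    if (!up) next
    if (is.null(best) || op$objective < best$objective) {
      best <- list(objective = op$objective, beta = op$minimum, step = step)
    }
  }
  beta <- best$beta; step <- best$step
  if (base %in% PURINES) {
    c6 <- .PRIMARY_PU - R6 * c(cos(beta), sin(beta))
    hx <- .ngon(c6, R6, beta, step, 0:5)
    rownames(hx) <- c("N1", "C2", "N3", "C4", "C5", "C6")
    mE <- (hx["C4", ] + hx["C5", ]) / 2
    a5 <- .RING_BOND / (2 * tan(pi / 5))
    R5 <- .RING_BOND / (2 * sin(pi / 5))
    c5 <- mE + a5 * .unit2(mE - c6)
    a4 <- atan2(hx["C4", 2] - c5[2], hx["C4", 1] - c5[1])
    aC5 <- atan2(hx["C5", 2] - c5[2], hx["C5", 1] - c5[1])
    d <- atan2(sin(aC5 - a4), cos(aC5 - a4))
    pent <- .ngon(c5, R5, a4, -d, 1:3)   # N9, C8, N7 stepping away from C5
    rownames(pent) <- c("N9", "C8", "N7")
    out <- rbind(hx, pent)
    # Watson-Crick exocyclic sites sit on the vertical pair edge through the
    # primary site, 0.225 nm above/below it, so every H-bond pair spans the
    # same 0.29 nm gap
    edge_up <- .PRIMARY_PU + c(0, 0.225)
    edge_dn <- .PRIMARY_PU - c(0, 0.225)
    if (base == "A") {
      out <- rbind(out, N6 = edge_up)
    } else {
      out <- rbind(out, O6 = edge_up, N2 = edge_dn)
    }
  } else {
    cc <- .PRIMARY_PY - R6 * c(cos(beta + 2 * step), sin(beta + 2 * step))
    hx <- .ngon(cc, R6, beta, step, 0:5)
    rownames(hx) <- c("N1", "C2", "N3", "C4", "C5", "C6")
    out <- hx
    exo <- function(at, len) out[at, ] + len * .unit2(out[at, ] - cc)
    edge_up <- .PRIMARY_PY + c(0, 0.225)
    edge_dn <- .PRIMARY_PY - c(0, 0.225)
    out <- rbind(out, O2 = edge_dn)
    if (base == "T") {
      out <- rbind(out, O4 = edge_up, C7 = exo("C5", 0.15))
    } else {
      out <- rbind(out, N4 = edge_up)
    }
  }
  out
}

.BASE_H <- list(
  A = c(C2 = 1, C8 = 1, N6 = 2),
  G = c(C8 = 1, N1 = 1, N2 = 2),
  C = c(N4 = 2, C5 = 1, C6 = 1),
  T = c(N3 = 1, C6 = 1, C7 = 3)
)

# Full strand-A nucleotide template for one base: data.frame with local
# (x, y, z) in the bp frame, element, united-atom mass, and rep flag.
.nt_template_one <- function(base) {
  phi0 <- atan2(.C1_POS[2], .C1_POS[1])
  bb <- .BACKBONE
  bbx <- data.frame(
    name = bb$name, element = bb$element,
    x = bb$r * cos(phi0 + bb$dphi * pi / 180),
    y = bb$r * sin(phi0 + bb$dphi * pi / 180),
    z = bb$z,
    mass = ATOMIC_MASS[bb$element] + bb$nH * ATOMIC_MASS["H"],
    stringsAsFactors = FALSE
  )
  ring <- .base_ring(base)
  nH <- .BASE_H[[base]]
  el <- substr(rownames(ring), 1, 1)
  bx <- data.frame(
    name = rownames(ring), element = el,
    x = ring[, 1], y = ring[, 2], z = 0,
    mass = ATOMIC_MASS[el] + ifelse(rownames(ring) %in% names(nH),
                                    nH[rownames(ring)], 0) * ATOMIC_MASS["H"],
    stringsAsFactors = FALSE
  )
  out <- rbind(bbx, bx)
  glyc <- if (base %in% PURINES) "N9" else "N1"
  out$rep <- out$name %in% c("P", "C4'", "C1'", BASE_BEADS[[base]])
  # map representative bead names: backbone primes dropped for bead ids
  out$bead <- ifelse(out$rep, sub("'", "", out$name), NA_character_)
  out$glyc <- out$name == glyc
  rownames(out) <- NULL
  out
}

.template_cache <- new.env(parent = emptyenv())

#' Nucleotide template for one base (strand-A orientation)
#'
#' Returns the idealized atom layout of a single nucleotide in the local
#' base-pair frame, including united-atom masses and the representative-atom
#' flags used by the coarse grainer.
#'
#' @param base One of "A", "C", "G", "T".
#' @return data.frame with columns name, element, x, y, z (nm), mass (amu),
#'   rep (logical), bead (bead id or NA) and glyc (glycosidic atom flag).
#' @export
nt_template <- function(base) {
  if (!base %in% c("A", "C", "G", "T")) {
    abort_dnanma(sprintf("unknown base '%s'", base), "dnanma_invalid_input")
  }
  key <- paste0("nt_", base)
  if (is.null(.template_cache[[key]])) {
    .template_cache[[key]] <- .nt_template_one(base)
  }
  .template_cache[[key]]
}

#' Base-pair template
#'
#' Atoms of a full Watson-Crick pair in the bp frame.  The strand-B
#' nucleotide is the dyad image (180 degree rotation about y) of the
#' complementary base's strand-A template, so every template pair is exactly
#' twofold symmetric.
#'
#' @param base_a Base identity on strand A.
#' @return data.frame as [nt_template()] plus a `strand` column ("A"/"B")
#'   and a `base` column.
#' @export
bp_template <- function(base_a) {
  key <- paste0("bp_", base_a)
  if (!is.null(.template_cache[[key]])) return(.template_cache[[key]])
  a <- nt_template(base_a)
  b <- nt_template(COMPLEMENT[[base_a]])
  a$strand <- "A"; a$base <- base_a
  b$strand <- "B"; b$base <- COMPLEMENT[[base_a]]
  b$x <- -b$x; b$z <- -b$z            # dyad: rotate pi about y
  out <- rbind(a, b)
  rownames(out) <- NULL
  .template_cache[[key]] <- out
  out
}

# residue mass of an internal (phosphate-bearing) nucleotide, amu
.residue_mass <- function(base) sum(nt_template(base)$mass)
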