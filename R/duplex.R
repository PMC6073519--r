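# Placement of base-pair templates along straight and circular-arc helical
# frames.  All builders funnel through .place_segment(), which instantiates
# the (exactly dyad-symmetric) bp templates bp-by-bp, so the symmetry
# properties of an assembly reduce to symmetry properties of the frames.

# engine: list(type = "straight", origin, axis, y0, rise, twist, s0)
#         s-th bp center at origin + axis * rise * s, twist angle twist*s
#         about `axis` with reference frame (x0 = y0 x axis, y0);
#     or  list(type = "arc", radius, theta0, dtheta, rise, twist, psi0)
#         bp k at ring angle theta0 + (k-1)*dtheta about the global z axis,
#         twist angle psi0 + twist*(k-1); template z offsets follow the arc.
.place_segment <- function(n_bp, seq_a, engine,
                           present_a = rep(TRUE, n_bp), present_b = rep(TRUE, n_bp),
                           strand_a = "A", strand_b = "B",
                           role_a = "duplex", role_b = role_a,
                           sticky_a = rep(FALSE, n_bp), sticky_b = rep(FALSE, n_bp),
                           copy_a = 1L, copy_b = copy_a,
                           ord_a = seq_len(n_bp), ord_b = n_bp + 1L - seq_len(n_bp),
                           seg = "seg", nt_start = 1L) {
  stopifnot(n_bp >= 1, length(seq_a) == n_bp)
  if (length(role_a) == 1) role_a <- rep(role_a, n_bp)
  if (length(role_b) == 1) role_b <- rep(role_b, n_bp)
  if (length(copy_a) == 1) copy_a <- rep(as.integer(copy_a), n_bp)
  if (length(copy_b) == 1) copy_b <- rep(as.integer(copy_b), n_bp)
  tw <- engine$twist * pi / 180
  parts <- vector("list", n_bp)
  pair_a <- pair_b <- integer(0)
  nt_id <- nt_start - 1L
  for (k in seq_len(n_bp)) {
    tpl <- bp_template(seq_a[k])
    keep <- (tpl$strand == "A" & present_a[k]) | (tpl$strand == "B" & present_b[k])
    if (!any(keep)) next
    tpl <- tpl[keep, , drop = FALSE]
    loc <- as.matrix(tpl[, c("x", "y", "z")])
    if (engine$type == "straight") {
      s <- engine$s0 + (k - 1)
      psi <- tw * s
      ax <- .unit(engine$axis); y0 <- .unit(engine$y0)
      x0 <- c(y0[2] * ax[3] - y0[3] * ax[2],
              y0[3] * ax[1] - y0[1] * ax[3],
              y0[1] * ax[2] - y0[2] * ax[1])        # x0 = y0 x axis
      xr <- cos(psi); sr <- sin(psi)
      exl <- xr * x0 + sr * y0                      # rotated x axis
      eyl <- -sr * x0 + xr * y0
      pos <- matrix(engine$origin, nrow(loc), 3, byrow = TRUE) +
        outer(engine$rise * s + loc[, 3], ax) +
        loc[, 1] %o% exl + loc[, 2] %o% eyl
    } else {
      th <- engine$theta0 + (k - 1) * engine$dtheta + loc[, 3] / engine$radius
      psi <- engine$psi0 + tw * (k - 1)
      radial <- engine$radius + loc[, 1] * sin(psi) + loc[, 2] * cos(psi)
      vert <- loc[, 1] * cos(psi) - loc[, 2] * sin(psi)
      pos <- cbind(radial * cos(th), radial * sin(th), vert)
    }
    sa <- if (length(strand_a) == 1) strand_a else strand_a[k]
    sb <- if (length(strand_b) == 1) strand_b else strand_b[k]
    ids <- integer(2)
    isA <- tpl$strand == "A"
    df <- data.frame(
      x = pos[, 1], y = pos[, 2], z = pos[, 3],
      element = tpl$element, name = tpl$name, mass = tpl$mass,
      nt = NA_integer_,
      strand = ifelse(isA, sa, sb),
      ord = ifelse(isA, ord_a[k], ord_b[k]),
      base = tpl$base,
      copy = ifelse(isA, copy_a[k], copy_b[k]),
      role = ifelse(isA, role_a[k], role_b[k]),
      sticky = ifelse(isA, sticky_a[k], sticky_b[k]),
      rep = tpl$rep, bead = tpl$bead, glyc = tpl$glyc,
      seg = seg, bp = k,
      stringsAsFactors = FALSE
    )
    if (present_a[k]) { nt_id <- nt_id + 1L; df$nt[tpl$strand == "A"] <- nt_id; ids[1] <- nt_id }
    if (present_b[k]) { nt_id <- nt_id + 1L; df$nt[tpl$strand == "B"] <- nt_id; ids[2] <- nt_id }
    if (present_a[k] && present_b[k]) { pair_a <- c(pair_a, ids[1]); pair_b <- c(pair_b, ids[2]) }
    parts[[k]] <- df
  }
  list(atoms = do.call(rbind, parts),
       pairs = data.frame(nt_a = pair_a, nt_b = pair_b),
       links = data.frame(nt_a = integer(), nt_b = integer()),
       nt_next = nt_id + 1L)
}

#' Build an ideal straight B-form duplex
#'
#' Generates a double-stranded helix fragment with the stated number of base
#' pairs, rise, twist and the package's idealized nucleotide templates.
#'
#' @param bp_count Number of base pairs (>= 1).
#' @param seq_a Strand-A base sequence 5' to 3'; recycled/truncated to
#'   `bp_count`.  Default is a repeating ACGT motif.
#' @param origin,axis,y0 Rigid placement: position of the first base pair,
#'   helix axis direction, and reference y direction (defaults: origin,
#'   z axis, y axis).
#' @param rise,twist Helix rise (nm/bp) and twist (degrees/bp).
#' @param role Segment role annotation for every nucleotide.
#' @return A [fine_model()] fragment with `2 * bp_count` nucleotides.
#' @export
build_duplex <- function(bp_count, seq_a = NULL,
                         origin = c(0, 0, 0), axis = c(0, 0, 1), y0 = c(0, 1, 0),
                         rise = dnanma_defaults()$rise,
                         twist = dnanma_defaults()$twist,
                         role = "duplex") {
  if (!is.numeric(bp_count) || bp_count < 1) {
    abort_dnanma("bp_count must be >= 1", "dnanma_invalid_design")
  }
  bp_count <- as.integer(bp_count)
  if (is.null(seq_a)) seq_a <- c("A", "C", "G", "T")[(seq_len(bp_count) - 1) %% 4 + 1]
  seq_a <- rep(seq_a, length.out = bp_count)
  eng <- list(type = "straight", origin = origin, axis = axis, y0 = y0,
              rise = rise, twist = twist, s0 = 0)
  seg <- .place_segment(bp_count, seq_a, eng, role_a = role)
  fine_model(seg$atoms, seg$pairs, meta = list(kind = "duplex", bp = bp_count,
                                               rise = rise, twist = twist))
}

# palindromic strand-A sequence of even length n: b(s) = complement(b(-s)),
# needed so buckyball edge duplexes are exactly symmetric under the
# icosahedral 2-fold axes through hexagon-hexagon edge midpoints
.palindromic_seq <- function(n) {
  stopifnot(n %% 2 == 0)
  half <- c("A", "C", "G", "T")[(seq_len(n / 2) - 1) %% 4 + 1]
  c(rev(unname(COMPLEMENT[half])), half)
}
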