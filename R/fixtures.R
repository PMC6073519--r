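# Desk-scale fixtures with known properties: a two-bead dimer with a
# closed-form eigenvalue, a floppy linear chain, small C_q toy rings
# amenable to dense full-spectrum oracles, and the tetrahedral mini-ball.

# one circular duplex arc split into q congruent tiles by sticky nicks
.toy_ring <- function(q, n = 6, stk = 2) {
  p <- dnanma_defaults()
  N <- q * n
  R <- N * p$rise / (2 * pi)
  turns <- max(1, round(n * p$twist / 360))
  g <- seq_len(N) - 1L
  in_tile <- g %% n
  frag_a <- g %/% n + 1L
  frag_b <- ((g - stk) %% N) %/% n + 1L
  pos_b <- (g - ((frag_b - 1L) * n + stk)) %% N
  eng <- list(type = "arc", radius = R, theta0 = pi / N, dtheta = 2 * pi / N,
              rise = p$rise, twist = turns * 360 / n, psi0 = 0)
  seg <- .place_segment(
    N, .arc_motif(n)[in_tile + 1L], eng,
    strand_a = sprintf("toy.A%02d", frag_a),
    strand_b = sprintf("toy.B%02d", frag_b),
    role_a = "inner_circle",
    sticky_a = in_tile < stk, sticky_b = in_tile < stk,
    copy_a = frag_a, copy_b = frag_b,
    ord_a = g + 1L, ord_b = n - pos_b,
    seg = "toy", nt_start = 1L
  )
  atoms <- .drop_5p_phosphates(seg$atoms)
  full <- fine_model(atoms, seg$pairs,
                     meta = list(kind = sprintf("toy_ring_c%d", q), radius = R,
                                 group_name = sprintf("C%d", q)))
  # re-assemble from the copy-1 tile so every copy repeats the same local
  # atom ordering (the wrap-around strand fragment of the directly built
  # circle would otherwise order differently)
  tile <- .extract_copy(full, 1L, meta = full$meta)
  assemble(tile, cyclic_group(q))
}

#' Generate a deterministic test fixture
#'
#' @param kind One of "dimer", "chain", "toy_ring_c3", "toy_ring_c4",
#'   "toy_ring_c6", "mini_ball".
#' @param size Chain length (chain fixture only).
#' @return A `dnanma_fixture`: list with `kind`, `fine` (a [fine_model()]
#'   where applicable), `cg` (a [cg_model()]), and `meta` holding the
#'   expected properties (group order, rigid-mode count, closed-form
#'   eigenvalues where known).
#' @export
generate_fixture <- function(kind = c("dimer", "chain", "toy_ring_c3",
                                      "toy_ring_c4", "toy_ring_c6", "mini_ball"),
                             size = 5) {
  kind <- match.arg(kind)
  if (kind == "dimer") {
    beads <- data.frame(
      x = c(0, 1), y = 0, z = 0, mass = 100, nt = 1:2, strand = "d", ord = 1:2,
      copy = 1L, role = "toy", sticky = FALSE, bead = "P", base = "A", seg = "toy")
    springs <- data.frame(i = 1L, j = 2L, type = "covalent",
                          k = spring_constants()[["covalent"]], rest = 1)
    cg <- cg_model(beads, springs, meta = list(kind = "dimer"))
    return(structure(list(
      kind = kind, fine = NULL, cg = cg,
      meta = list(zero_modes = 5L,
                  lambda_nonzero = 2 * springs$k * AMU_PS2_PER_NM / beads$mass[1])),
      class = "dnanma_fixture"))
  }
  if (kind == "chain") {
    if (size > 500) abort_dnanma("chain fixture limited to 500 beads; use a builder",
                                 "dnanma_invalid_input")
    beads <- data.frame(
      x = 0.5 * (seq_len(size) - 1), y = 0, z = 0, mass = 100,
      nt = seq_len(size), strand = "c", ord = seq_len(size),
      copy = 1L, role = "toy", sticky = FALSE, bead = "P", base = "A", seg = "toy")
    springs <- data.frame(i = seq_len(size - 1), j = seq_len(size - 1) + 1L,
                          type = "covalent",
                          k = spring_constants()[["covalent"]], rest = 0.5)
    cg <- cg_model(beads, springs, meta = list(kind = "chain"))
    # a straight chain of axial springs is transversely floppy:
    # rank(K) = size - 1, so 2 * size + 1 zero modes
    return(structure(list(
      kind = kind, fine = NULL, cg = cg,
      meta = list(zero_modes = 2L * size + 1L)), class = "dnanma_fixture"))
  }
  if (kind == "mini_ball") {
    fine <- build_mini_ball()
    cg <- coarse_grain(fine)
    return(structure(list(
      kind = kind, fine = fine, cg = cg,
      meta = list(group = tetrahedral_group(), zero_modes = 6L,
                  euler = list(vertices = 12L, edges = 18L, faces = 8L))),
      class = "dnanma_fixture"))
  }
  q <- as.integer(sub("toy_ring_c", "", kind))
  fine <- .toy_ring(q)
  cg <- coarse_grain(fine)
  if (nrow(cg$beads) > 500) {
    abort_dnanma("toy ring fixture exceeds 500 beads", "dnanma_invalid_input")
  }
  structure(list(
    kind = kind, fine = fine, cg = cg,
    meta = list(group = cyclic_group(q), zero_modes = 6L, q = q)),
    class = "dnanma_fixture")
}
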