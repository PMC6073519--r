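# Heavy structures are built once per test run and shared across files.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

ring_model <- function(variant) {
  cached(paste0("ring_", variant), build_ring(ring_design(variant)))
}
ring_cg <- function(variant) {
  cached(paste0("ringcg_", variant), coarse_grain(ring_model(variant)))
}
ring_modes <- function(variant) {
  cached(paste0("ringms_", variant), {
    ms <- suppressWarnings(solve_modes(ring_cg(variant), n_modes = 16))
    label_modes(ms, ring_cg(variant), "ring", n_label = 10)
  })
}
toy_fixture <- function(q) {
  cached(paste0("toy_c", q), generate_fixture(paste0("toy_ring_c", q)))
}
tile_cg <- function() {
  cached("tilecg", coarse_grain(cached("tile", build_3ps_tile())))
}
tile_modes <- function() {
  cached("tilems", {
    ms <- suppressWarnings(solve_modes(tile_cg(), n_modes = 18))
    label_modes(ms, tile_cg(), "tile", n_label = 10)
  })
}
ball_model <- function() cached("ball", build_buckyball())
ball_cg <- function() cached("ballcg", coarse_grain(ball_model()))
ball_modes <- function() {
  cached("ballms", {
    ms <- scenm_modes(ball_cg(), icosahedral_group(), n_modes = 12)
    label_modes(ms, ball_cg(), "buckyball", n_label = 10)
  })
}
mini_fixture <- function() cached("mini", generate_fixture("mini_ball"))

# dense full-spectrum generalized eigenvalues, assembled independently of
# the package solver path (direct construction of the mass-weighted
# Hessian from the spring list, full eigendecomposition)
dense_spectrum <- function(cg) {
  b <- cg$beads; s <- cg$springs
  n <- nrow(b)
  xyz <- as.matrix(b[, c("x", "y", "z")])
  K <- matrix(0, 3 * n, 3 * n)
  for (r in seq_len(nrow(s))) {
    i <- s$i[r]; j <- s$j[r]
    e <- (xyz[i, ] - xyz[j, ]) / s$rest[r]
    blk <- s$k[r] * (e %o% e)
    ii <- 3 * (i - 1) + 1:3; jj <- 3 * (j - 1) + 1:3
    K[ii, ii] <- K[ii, ii] + blk
    K[jj, jj] <- K[jj, jj] + blk
    K[ii, jj] <- K[ii, jj] - blk
    K[jj, ii] <- K[jj, ii] - blk
  }
  conv <- 602.2140857
  dh <- rep(1 / sqrt(b$mass), each = 3)
  Kt <- conv * t(t(K * dh) * dh)
  sort(eigen((Kt + t(Kt)) / 2, symmetric = TRUE, only.values = TRUE)$values)
}
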