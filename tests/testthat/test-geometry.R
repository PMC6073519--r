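# Geometry: duplex generation, symmetry groups, tiles, assembly,
# validation, measurement, and polyhedral topology.

test_that("ideal duplex obeys B-form bookkeeping", {
  d <- build_duplex(10)
  expect_equal(length(unique(d$atoms$nt)), 20)
  expect_equal(nrow(d$pairs), 10)
  # length additivity: contour = bp_count x rise; bp centers span (n-1) x rise
  ctr_z <- tapply(d$atoms$z[d$atoms$glyc], d$atoms$bp[d$atoms$glyc], mean)
  expect_equal(10 * 0.34, 3.4)
  expect_equal(max(d$atoms$bp) * 0.34, 3.4)
  expect_equal(unname(diff(range(ctr_z))), 9 * 0.34, tolerance = 0.05)

  d1 <- build_duplex(1)
  expect_equal(length(unique(d1$atoms$nt)), 2)
  expect_equal(nrow(d1$pairs), 1)

  # a full 360-degree turn reproduces the first base pair one pitch higher
  dt <- build_duplex(11, seq_a = rep("A", 11), twist = 36)
  a1 <- dt$atoms[dt$atoms$bp == 1, ]
  a11 <- dt$atoms[dt$atoms$bp == 11, ]
  o1 <- order(a1$strand, a1$name); o11 <- order(a11$strand, a11$name)
  shift <- as.matrix(a11[o11, c("x", "y", "z")]) -
    as.matrix(a1[o1, c("x", "y", "z")])
  expect_lt(max(abs(shift[, 1:2])), 1e-9)
  expect_equal(unname(shift[, 3]), rep(10 * 0.34, nrow(shift)), tolerance = 1e-9)

  expect_error(build_duplex(0), class = "dnanma_invalid_design")
})

test_that("symmetry groups are proper closed rotation groups", {
  expect_silent(check_group(cyclic_group(12)))
  ico <- icosahedral_group()
  expect_equal(ico$order, 60)
  expect_silent(check_group(ico))
  tet <- tetrahedral_group()
  expect_equal(tet$order, 12)
  expect_silent(check_group(tet))
  expect_equal(cyclic_group(4)$rotations[[1]], diag(3))
})

test_that("assembled tile copies are congruent isometries", {
  for (mdl in list(ring_model("r1c"), toy_fixture(4)$fine)) {
    a <- mdl$atoms
    copies <- sort(unique(a$copy))
    q <- length(copies)
    g <- cyclic_group(q)
    a1 <- a[a$copy == 1, ]; o1 <- order(a1$nt, a1$name)
    x1 <- as.matrix(a1[o1, c("x", "y", "z")])
    for (i in c(2, q)) {
      ai <- a[a$copy == i, ]; oi <- order(ai$nt, ai$name)
      xi <- as.matrix(ai[oi, c("x", "y", "z")])
      expect_lt(max(abs(xi - x1 %*% t(g$rotations[[i]]))), 1e-9)
      # intra-tile distances identical across copies (congruence)
      sub <- seq(1, nrow(x1), length.out = 40)
      expect_lt(max(abs(dist(xi[sub, ]) - dist(x1[sub, ]))), 1e-9)
    }
  }
})

test_that("assembling with the identity group is the identity operation", {
  tile <- build_tile(ring_design("r1c"))
  asm <- assemble(tile, cyclic_group(1))
  expect_equal(asm$atoms$x, tile$atoms$x)
  expect_equal(asm$atoms$y, tile$atoms$y)
  expect_equal(asm$atoms$z, tile$atoms$z)
  expect_equal(nrow(asm$pairs), nrow(tile$pairs))
})

test_that("applying a group element permutes tile copies", {
  mdl <- toy_fixture(3)$fine
  g <- cyclic_group(3)
  a <- mdl$atoms
  rot <- as.matrix(a[, c("x", "y", "z")]) %*% t(g$rotations[[2]])
  # rotated copy 1 must coincide with copy 2 as a point set
  r1 <- rot[a$copy == 1, , drop = FALSE]
  c2 <- as.matrix(a[a$copy == 2, c("x", "y", "z")])
  ord1 <- order(a$nt[a$copy == 1], a$name[a$copy == 1])
  ord2 <- order(a$nt[a$copy == 2], a$name[a$copy == 2])
  expect_lt(max(abs(r1[ord1, ] - c2[ord2, ])), 1e-9)
})

test_that("flat three-point-star tile has threefold arm symmetry", {
  tile <- cached("tile", build_3ps_tile())
  a <- tile$atoms
  R <- rotation_about(c(0, 0, 1), 2 * pi / 3)
  a1 <- a[a$seg == "arm1", ]; a2 <- a[a$seg == "arm2", ]
  o1 <- order(a1$ord, a1$strand, a1$name); o2 <- order(a2$ord, a2$strand, a2$name)
  expect_lt(max(abs(as.matrix(a1[o1, c("x", "y", "z")]) %*% t(R) -
                      as.matrix(a2[o2, c("x", "y", "z")]))), 1e-9)
})

test_that("open-form R1 tiles carry the 8-nt single-stranded domain", {
  a <- ring_model("r1o")$atoms
  ss <- unique(a$nt[a$role == "single_stranded"])
  expect_equal(length(ss), 8 * 12)
  expect_equal(length(unique(a$nt[a$role == "single_stranded" & a$copy == 1])), 8)
  # closed form has none
  expect_equal(sum(ring_model("r1c")$atoms$role == "single_stranded"), 0)
})

test_that("built assemblies validate clash-free with in-band H-bonds", {
  for (mdl in list(ring_model("r1c"), ring_model("r1o"), ball_model())) {
    rep <- cached(paste0("val_", mdl$meta$kind, nrow(mdl$atoms)),
                  validate_structure(mdl))
    expect_equal(nrow(rep$clash_pairs), 0)
    expect_true(all(rep$hbonds$d >= 0.25 & rep$hbonds$d <= 0.35))
    expect_gt(rep$min_dist, 0.25)
  }
})

test_that("sticky-end interfaces pair completely by construction", {
  rep <- cached(paste0("val_", "ring", nrow(ring_model("r1c")$atoms)),
                validate_structure(ring_model("r1c")))
  des <- ring_design("r1c")
  # every tile interface hybridizes both arc overhangs completely
  expect_equal(nrow(rep$sticky), 12)
  expect_true(all(rep$sticky$n_pairs == 2 * des$sticky_len))
  expect_true(all(rep$sticky$n_ok == rep$sticky$n_hbonds))
})

test_that("coincident non-bonded atoms are reported as clashes", {
  d1 <- build_duplex(2, seq_a = c("A", "A"))
  d2 <- build_duplex(2, seq_a = c("A", "A"))
  d2$atoms$nt <- d2$atoms$nt + 10L
  d2$atoms$strand <- paste0(d2$atoms$strand, "2")
  d2$atoms$x <- d2$atoms$x + 0.05   # nearly coincident copy
  both <- fine_model(rbind(d1$atoms, d2$atoms),
                     rbind(d1$pairs, data.frame(nt_a = d2$pairs$nt_a + 10L,
                                                nt_b = d2$pairs$nt_b + 10L)))
  rep <- validate_structure(both)
  expect_gt(nrow(rep$clash_pairs), 0)
})

test_that("ring diameters reduce to 2r for a plain circle", {
  th <- seq(0, 2 * pi, length.out = 13)[-13]
  r <- 5
  tpl <- build_duplex(1)$atoms
  rows <- list()
  for (k in seq_along(th)) {
    at <- tpl
    at$x <- r * cos(th[k]); at$y <- r * sin(th[k]); at$z <- 0
    at$nt <- at$nt + 2L * (k - 1L)
    at$strand <- paste0(at$strand, k)
    at$role <- "inner_circle"
    rows[[k]] <- at
  }
  atoms <- do.call(rbind, rows)
  pairs <- data.frame(nt_a = seq(1, 24, by = 2), nt_b = seq(2, 24, by = 2))
  mdl <- fine_model(atoms, pairs)
  m <- measure_ring_diameters(mdl)
  expect_equal(m$outer, 2 * r)
  expect_equal(m$inner, 2 * r)
  # no inner_circle annotation -> unsupported structure
  atoms$role <- "arm"
  expect_error(measure_ring_diameters(fine_model(atoms, pairs)),
               class = "dnanma_unsupported_structure")
})

test_that("tile adjacency topology recovers the polyhedra", {
  tg <- tile_graph(ball_model())
  topo <- assembly_topology(tg$centers, tg$interfaces)
  expect_identical(topo$vertices, 60L)
  expect_identical(topo$edges, 90L)
  expect_identical(topo$faces, 32L)
  expect_identical(topo$faces_by_size[["5"]], 12L)
  expect_identical(topo$faces_by_size[["6"]], 20L)

  tgm <- tile_graph(mini_fixture()$fine)
  tm <- assembly_topology(tgm$centers, tgm$interfaces)
  expect_identical(c(tm$vertices, tm$edges, tm$faces), c(12L, 18L, 8L))
  expect_identical(tm$faces_by_size[["3"]], 4L)
  expect_identical(tm$faces_by_size[["6"]], 4L)

  tgr <- tile_graph(ring_model("r1c"))
  tr <- assembly_topology(tgr$centers, tgr$interfaces)
  expect_identical(c(tr$vertices, tr$edges), c(12L, 12L))
})
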