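# Coarse-graining: representative selection, lumped masses, spring network.

test_that("per-base bead counts follow the purine/pyrimidine rule", {
  d3 <- build_duplex(3, seq_a = c("G", "A", "G"))   # middle bp: A . T
  b <- select_representatives(d3)
  mid <- b[b$ord == 2, ]
  expect_equal(sum(mid$base == "A"), 7)   # purine: P C4 C1 + 4 base sites
  expect_equal(sum(mid$base == "T"), 6)   # pyrimidine: P C4 C1 + 3
  d3c <- build_duplex(3, seq_a = c("A", "C", "A"))
  bc <- select_representatives(d3c)
  expect_equal(sum(bc$ord == 2 & bc$base == "C"), 6)
  expect_equal(sum(bc$ord == 2 & bc$base == "G"), 7)
})

test_that("a 10-bp G.C duplex with terminal phosphates has 130 beads", {
  d10 <- build_duplex(10, seq_a = rep("G", 10))   # fragment keeps 5' P
  expect_equal(nrow(select_representatives(d10)), 10 * 7 + 10 * 6)
})

test_that("5'-terminal nucleotides built without phosphate have no P bead", {
  b <- select_representatives(ring_model("r1c"))
  starts <- tapply(b$ord, b$strand, min)
  for (s in names(starts)[1:5]) {
    expect_false(any(b$bead[b$strand == s & b$ord == starts[[s]]] == "P"))
  }
})

test_that("lumped masses conserve nucleotide and total mass", {
  cg <- ring_cg("r1c")
  expect_equal(total_mass(cg), total_mass(ring_model("r1c")), tolerance = 1e-12)
  # internal dT carries the dTMP residue mass
  d3 <- build_duplex(3, seq_a = c("A", "A", "A"))
  cg3 <- coarse_grain(d3)
  bt <- cg3$beads
  mT <- sum(bt$mass[bt$base == "T" & bt$ord == 2])
  expect_equal(mT, 304.2, tolerance = 0.05)
  # lumping only adds mass: every P bead is at least a bare P atom
  expect_true(all(cg3$beads$mass[cg3$beads$bead == "P"] >= 30.97))
})

test_that("spring constants follow the 1:10:100 chemical-bond ratio", {
  ks <- spring_constants()
  expect_identical(unname(ks[c("van_der_waals", "hydrogen", "covalent")]),
                   c(7, 70, 700))
  expect_equal(unname(ks["hydrogen"] / ks["van_der_waals"]), 10)
  expect_equal(unname(ks["covalent"] / ks["van_der_waals"]), 100)
  cg <- ring_cg("r1c")
  expect_true(all(cg$springs$k %in% c(7, 70, 700)))
  got <- tapply(cg$springs$k, cg$springs$type, unique)
  expect_equal(unname(got[["van_der_waals"]]), 7)
  expect_equal(unname(got[["hydrogen"]]), 70)
  expect_equal(unname(got[["covalent"]]), 700)
})

test_that("beads beyond the cutoff get no van der Waals spring", {
  d1 <- build_duplex(2, seq_a = c("A", "A"))
  d2 <- build_duplex(2, seq_a = c("A", "A"))
  d2$atoms$nt <- d2$atoms$nt + 4L
  d2$atoms$strand <- paste0(d2$atoms$strand, "2")
  d2$atoms$x <- d2$atoms$x + 5    # far beyond any cutoff
  both <- fine_model(rbind(d1$atoms, d2$atoms),
                     rbind(d1$pairs, data.frame(nt_a = d2$pairs$nt_a + 4L,
                                                nt_b = d2$pairs$nt_b + 4L)))
  cg <- coarse_grain(both, cutoff = 0.8)
  grp <- cg$beads$nt <= 4
  cross <- grp[cg$springs$i] != grp[cg$springs$j]
  expect_equal(sum(cross), 0)
})

test_that("paired bases carry hydrogen springs", {
  dG <- build_duplex(1, seq_a = "G")
  cg <- coarse_grain(dG)
  expect_gte(sum(cg$springs$type == "hydrogen"), 1)
  # the G.C hydrogen springs connect Watson-Crick bead sites
  h <- cg$springs[cg$springs$type == "hydrogen", ]
  bd <- cg$beads$bead
  expect_true(all(paste(pmin(bd[h$i], bd[h$j]), pmax(bd[h$i], bd[h$j])) %in%
                    c("N1 N3", "N4 O6")))
})

test_that("each bead pair carries at most one spring, strongest class first", {
  cg <- ring_cg("r1c")
  expect_equal(anyDuplicated(cg$springs[, c("i", "j")]), 0)
  # covalently bonded short pairs are never downgraded to van der Waals
  short_cov <- cg$springs$type == "covalent" & cg$springs$rest < 0.8
  expect_gt(sum(short_cov), 0)
})

test_that("invalid inputs raise classed errors", {
  bad <- build_duplex(1)
  bad$atoms$base[1] <- "X"
  expect_error(select_representatives(bad), class = "dnanma_invalid_input")
  d <- build_duplex(2)
  b <- assign_lumped_masses(select_representatives(d), d)
  expect_error(build_spring_network(b, d, cutoff = -1),
               class = "dnanma_invalid_parameter")
})

test_that("coarse-graining commutes with the assembly symmetry", {
  cg <- toy_fixture(4)$cg
  g <- toy_fixture(4)$meta$group
  part <- partition_by_symmetry(cg, g)   # verifies positions AND masses
  expect_s3_class(part, "subunit_partition")
  expect_equal(part$q * part$m, nrow(cg$beads))
})

test_that("spring networks of assembled structures are connected", {
  for (cg in list(ring_cg("r1c"), toy_fixture(4)$cg, mini_fixture()$cg)) {
    g <- igraph::graph_from_edgelist(as.matrix(cg$springs[, c("i", "j")]),
                                     directed = FALSE)
    if (igraph::vcount(g) < nrow(cg$beads)) {
      g <- igraph::add_vertices(g, nrow(cg$beads) - igraph::vcount(g))
    }
    expect_true(igraph::is_connected(g))
  }
})
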