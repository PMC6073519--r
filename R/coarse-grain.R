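# Coarse-graining: representative atoms, lumped masses, and the typed
# spring network (van der Waals / hydrogen / covalent springs).

#' Construct a coarse-grained model
#'
#' Low-level constructor used by [coarse_grain()] and by the desk-scale
#' fixtures.
#'
#' @param beads data.frame with at least x, y, z (nm) and mass (amu);
#'   structure-level annotations (nt, strand, copy, role, sticky, bead,
#'   base) are optional.
#' @param springs data.frame with columns i, j (bead indices), k (N/m),
#'   type, rest (nm).
#' @param meta Named list.
#' @return Object of class `cg_model`.
#' @export
cg_model <- function(beads, springs, meta = list()) {
  stopifnot(all(beads$mass > 0), all(springs$i != springs$j))
  structure(list(beads = beads, springs = springs, meta = meta),
            class = "cg_model")
}

#' @export
print.cg_model <- function(x, ...) {
  cat("cg_model:", nrow(x$beads), "beads,", nrow(x$springs), "springs\n")
  if (nrow(x$springs)) print(table(x$springs$type))
  invisible(x)
}

#' Select representative atoms
#'
#' Picks the per-nucleotide representative atoms: three backbone sites
#' (P, C4', C1'; the P bead is absent on 5'-terminal nucleotides built
#' without a phosphate) plus three base sites for pyrimidines or four for
#' purines (the glycosidic nitrogen and the Watson-Crick edge sites).
#'
#' @param model A [fine_model()].
#' @return data.frame of beads (positions, own atom masses, annotations),
#'   ordered by tile copy, nucleotide, and bead rank.
#' @export
select_representatives <- function(model) {
  a <- model$atoms
  bad <- setdiff(unique(a$base), c("A", "C", "G", "T"))
  if (length(bad)) {
    abort_dnanma(paste("unknown base letter:", paste(bad, collapse = ", ")),
                 "dnanma_invalid_input")
  }
  b <- a[a$rep, , drop = FALSE]
  rank <- match(b$bead, c("P", "C4", "C1"))
  base_rank <- mapply(function(bd, bs) match(bd, BASE_BEADS[[bs]]), b$bead, b$base)
  rank[is.na(rank)] <- 3 + base_rank[is.na(rank)]
  b <- b[order(b$copy, b$nt, rank), , drop = FALSE]
  data.frame(
    x = b$x, y = b$y, z = b$z, mass = b$mass,
    nt = b$nt, strand = b$strand, ord = b$ord, copy = b$copy,
    role = b$role, sticky = b$sticky, bead = b$bead, base = b$base,
    seg = b$seg, stringsAsFactors = FALSE
  )
}

#' Assign lumped masses
#'
#' Adds every non-representative atom's mass to the nearest representative
#' bead of the same nucleotide, so the per-nucleotide (and total) mass is
#' conserved exactly.
#'
#' @param beads Bead table from [select_representatives()].
#' @param model The [fine_model()] the beads came from.
#' @return The bead table with lumped masses.
#' @export
assign_lumped_masses <- function(beads, model) {
  a <- data.table::as.data.table(model$atoms)
  nr <- a[rep == FALSE, .(nt, x, y, z, mass)]
  nr[, aid := .I]
  bt <- data.table::as.data.table(beads)
  bt[, bid := .I]
  if (!all(unique(nr$nt) %in% bt$nt)) {
    abort_dnanma("nucleotide with no representative bead", "dnanma_internal")
  }
  j <- merge(nr, bt[, .(nt, bx = x, by = y, bz = z, bid)], by = "nt",
             allow.cartesian = TRUE)
  j[, d2 := round((x - bx)^2 + (y - by)^2 + (z - bz)^2, 9)]
  # ties (atoms exactly equidistant from two beads by symmetry) break by
  # bead rank so the assignment is identical across symmetric copies
  pick <- j[order(aid, d2, bid), .SD[1], by = aid]
  add <- pick[, .(extra = sum(mass)), by = bid]
  out <- beads
  out$mass[add$bid] <- out$mass[add$bid] + add$extra
  out
}

#' Build the typed spring network
#'
#' Connects beads with springs according to chemical bond class: covalent
#' springs along each strand's backbone chain (P-C4-C1 within a nucleotide,
#' C1 to the glycosidic bead, glycosidic bead to the other base beads,
#' P to the preceding nucleotide's C4, and at designed junction links),
#' hydrogen springs between the Watson-Crick bead sites of paired bases
#' (including hybridized sticky ends), and van der Waals springs between all
#' remaining bead pairs within the cutoff.  Each pair carries at most one
#' spring; the strongest bond class wins.
#'
#' @param beads Lumped-mass bead table.
#' @param model The source [fine_model()].
#' @param cutoff van der Waals cutoff distance in nm (default 0.8).
#' @return A [cg_model()].
#' @export
build_spring_network <- function(beads, model, cutoff = dnanma_defaults()$cutoff) {
  if (!is.numeric(cutoff) || cutoff <= 0) {
    abort_dnanma("cutoff must be positive", "dnanma_invalid_parameter")
  }
  ks <- spring_constants()
  n <- nrow(beads)
  bt <- data.table::as.data.table(beads)
  bt[, bid := .I]
  key <- function(nt, bead) paste(nt, bead)
  lookup <- new.env(parent = emptyenv())
  invisible(mapply(function(k, v) assign(k, v, envir = lookup),
                   key(bt$nt, bt$bead), bt$bid))
  get_bid <- function(nt, bead) {
    k <- key(nt, bead)
    if (exists(k, envir = lookup)) get(k, envir = lookup) else NA_integer_
  }
  ii <- jj <- integer(0); ty <- character(0)
  add <- function(i, j, type) {
    ok <- !is.na(i) & !is.na(j)
    ii <<- c(ii, i[ok]); jj <<- c(jj, j[ok]); ty <<- c(ty, rep(type, sum(ok)))
  }
  # covalent: intra-nucleotide chain and base star
  nts <- bt[, .(base = base[1]), by = nt]
  glyc_of <- function(base) ifelse(base %in% PURINES, "N9", "N1")
  p_id <- vapply(nts$nt, function(x) get_bid(x, "P"), 1L)
  c4_id <- vapply(nts$nt, function(x) get_bid(x, "C4"), 1L)
  c1_id <- vapply(nts$nt, function(x) get_bid(x, "C1"), 1L)
  g_id <- mapply(function(x, b) get_bid(x, glyc_of(b)), nts$nt, nts$base)
  add(p_id, c4_id, "covalent")
  add(c4_id, c1_id, "covalent")
  add(c1_id, g_id, "covalent")
  for (b in c("A", "C", "G", "T")) {
    others <- setdiff(BASE_BEADS[[b]], glyc_of(b))
    sel <- nts$base == b
    for (o in others) {
      add(g_id[sel], vapply(nts$nt[sel], function(x) get_bid(x, o), 1L), "covalent")
    }
  }
  # covalent: inter-nucleotide backbone links (P of nt n+1 to C4 of nt n)
  ch <- bt[bead == "C1", .(nt, strand, ord)][order(strand, ord)]
  nxt <- ch[, .(nt_prev = nt[-.N], nt_next = nt[-1]), by = strand]
  if (nrow(nxt)) {
    add(vapply(nxt$nt_next, function(x) get_bid(x, "P"), 1L),
        vapply(nxt$nt_prev, function(x) get_bid(x, "C4"), 1L), "covalent")
  }
  # covalent: designed junction links (nearest bead pair of the linked nts)
  if (nrow(model$links)) {
    for (r in seq_len(nrow(model$links))) {
      ba <- bt[nt == model$links$nt_a[r]]; bb <- bt[nt == model$links$nt_b[r]]
      d2 <- outer(seq_len(nrow(ba)), seq_len(nrow(bb)), function(p, q) {
        (ba$x[p] - bb$x[q])^2 + (ba$y[p] - bb$y[q])^2 + (ba$z[p] - bb$z[q])^2
      })
      w <- arrayInd(which.min(d2), dim(d2))
      add(ba$bid[w[1]], bb$bid[w[2]], "covalent")
    }
  }
  # hydrogen: Watson-Crick bead sites of every paired base
  if (nrow(model$pairs)) {
    base_of <- stats::setNames(nts$base, nts$nt)
    pa <- model$pairs$nt_a; pb <- model$pairs$nt_b
    pu_first <- base_of[as.character(pa)] %in% PURINES
    pu <- ifelse(pu_first, pa, pb); py <- ifelse(pu_first, pb, pa)
    for (r in seq_along(pu)) {
      sites <- HSPRING_SITES[[paste0(base_of[as.character(pu[r])], ".",
                                     base_of[as.character(py[r])])]]
      if (is.null(sites)) next   # non-Watson-Crick pair: no hydrogen spring
      for (s in sites) add(get_bid(pu[r], s[1]), get_bid(py[r], s[2]), "hydrogen")
    }
  }
  # van der Waals: all remaining pairs within the cutoff
  xyz <- as.matrix(beads[, c("x", "y", "z")])
  np <- neighbor_pairs(xyz, cutoff)
  have <- unique(c((pmin(ii, jj) - 1) * n + pmax(ii, jj)))
  vkey <- (np$i - 1) * n + np$j
  np <- np[!(vkey %in% have)]
  springs <- data.frame(
    i = c(pmin(ii, jj), np$i), j = c(pmax(ii, jj), np$j),
    type = c(ty, rep("van_der_waals", nrow(np))),
    stringsAsFactors = FALSE
  )
  springs <- springs[!duplicated(springs[, c("i", "j")]), ]
  springs$k <- unname(ks[springs$type])
  springs$rest <- sqrt(
    (xyz[springs$i, 1] - xyz[springs$j, 1])^2 +
      (xyz[springs$i, 2] - xyz[springs$j, 2])^2 +
      (xyz[springs$i, 3] - xyz[springs$j, 3])^2
  )
  if (any(springs$rest < 1e-6)) {
    abort_dnanma("zero-length spring (coincident beads)", "dnanma_degenerate_geometry")
  }
  rownames(springs) <- NULL
  cg_model(beads, springs,
           meta = c(model$meta, list(cutoff = cutoff, n_fine_atoms = nrow(model$atoms))))
}

#' Coarse-grain a fine model
#'
#' Convenience pipeline: representative-atom selection, lumped-mass
#' assignment, and spring-network construction.
#'
#' @inheritParams build_spring_network
#' @param model A [fine_model()].
#' @return A [cg_model()].
#' @export
coarse_grain <- function(model, cutoff = dnanma_defaults()$cutoff) {
  beads <- select_representatives(model)
  beads <- assign_lumped_masses(beads, model)
  build_spring_network(beads, model, cutoff = cutoff)
}
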