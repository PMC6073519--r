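# Structure validation (hydrogen-bond lengths, sticky-end pairing, steric
# clashes), ring diameter measurement, and polyhedral tile-graph topology.

# nucleotide connectivity graph: backbone neighbors, Watson-Crick pairs,
# and designed junction links; returns a sparse pattern matrix marking nt
# pairs within `steps` bonds of each other
.nt_exclusion <- function(model, steps = 3) {
  a <- data.table::as.data.table(model$atoms)
  nts <- a[, .(strand = strand[1], ord = ord[1]), by = nt][order(nt)]
  id <- stats::setNames(seq_len(nrow(nts)), nts$nt)
  bb <- nts[order(strand, ord), .(a = nt[-.N], b = nt[-1],
                                  s1 = strand[-.N], s2 = strand[-1])]
  bb <- bb[s1 == s2]
  ea <- c(bb$a, model$pairs$nt_a, model$links$nt_a)
  eb <- c(bb$b, model$pairs$nt_b, model$links$nt_b)
  n <- nrow(nts)
  A <- sparseMatrix(i = c(id[as.character(ea)], id[as.character(eb)]),
                    j = c(id[as.character(eb)], id[as.character(ea)]),
                    x = 1, dims = c(n, n))
  E <- A
  P <- A
  for (s in seq_len(steps - 1)) {
    P <- P %*% A
    E <- E + P
  }
  list(E = E != 0, id = id)
}

#' Validate a built structure
#'
#' Computes, as the model-construction checks do: every base pair's
#' hydrogen-bond site distances, per tile-interface sticky-end pairing
#' counts, the minimum distance between non-bonded atoms, and the list of
#' clashing atom pairs (non-bonded atoms closer than the clash threshold;
#' "non-bonded" means the nucleotides are more than three steps apart in
#' the backbone/pairing/junction connectivity graph).
#'
#' @param model A [fine_model()].
#' @param clash_dist Clash threshold in nm.
#' @param hbond_band Acceptable H-bond length band in nm.
#' @return A `validation_report`: `hbonds`, `sticky`, `min_dist`,
#'   `clash_pairs`, and the thresholds used.
#' @export
validate_structure <- function(model,
                               clash_dist = dnanma_defaults()$clash_dist,
                               hbond_band = dnanma_defaults()$hbond_band) {
  a <- model$atoms
  if (!nrow(a)) abort_dnanma("empty model", "dnanma_invalid_input")
  # --- hydrogen-bond site distances for every pair
  key <- paste(a$nt, a$name)
  pos <- as.matrix(a[, c("x", "y", "z")])
  row_of <- stats::setNames(seq_len(nrow(a)), key)
  base_of <- stats::setNames(a$base, as.character(a$nt))
  copy_of <- stats::setNames(a$copy, as.character(a$nt))
  hb <- NULL
  if (nrow(model$pairs)) {
    pa <- model$pairs$nt_a; pb <- model$pairs$nt_b
    pu_first <- base_of[as.character(pa)] %in% PURINES
    pu <- ifelse(pu_first, pa, pb); py <- ifelse(pu_first, pb, pa)
    combo <- paste0(base_of[as.character(pu)], ".", base_of[as.character(py)])
    site_tab <- do.call(rbind, lapply(names(HBOND_SITES), function(cm) {
      data.frame(combo = cm,
                 s_pu = vapply(HBOND_SITES[[cm]], `[`, "", 1),
                 s_py = vapply(HBOND_SITES[[cm]], `[`, "", 2))
    }))
    pr_tab <- merge(data.frame(nt_a = pu, nt_b = py, combo = combo),
                    site_tab, by = "combo")
    i <- match(paste(pr_tab$nt_a, pr_tab$s_pu), key)
    j <- match(paste(pr_tab$nt_b, pr_tab$s_py), key)
    hb <- data.frame(nt_a = pr_tab$nt_a, nt_b = pr_tab$nt_b,
                     site = paste(pr_tab$s_pu, pr_tab$s_py, sep = "-"),
                     d = sqrt(rowSums((pos[i, , drop = FALSE] -
                                         pos[j, , drop = FALSE])^2)))
  }
  # --- sticky-end interface table (pairs across tile copies)
  sticky <- NULL
  if (nrow(model$pairs)) {
    ca <- copy_of[as.character(model$pairs$nt_a)]
    cb <- copy_of[as.character(model$pairs$nt_b)]
    cross <- ca != cb
    if (any(cross)) {
      st <- data.table::data.table(
        copy_a = pmin(ca[cross], cb[cross]),
        copy_b = pmax(ca[cross], cb[cross]),
        nt_a = model$pairs$nt_a[cross], nt_b = model$pairs$nt_b[cross])
      hbk <- data.table::as.data.table(hb)
      hbk[, keyp := paste(pmin(nt_a, nt_b), pmax(nt_a, nt_b))]
      st[, keyp := paste(pmin(nt_a, nt_b), pmax(nt_a, nt_b))]
      cnt <- hbk[st, on = "keyp"][, .(
        n_hbonds = .N,
        n_ok = sum(d >= hbond_band[1] & d <= hbond_band[2])
      ), by = .(copy_a, copy_b)]
      npair <- st[, .(n_pairs = .N), by = .(copy_a, copy_b)]
      sticky <- as.data.frame(merge(npair, cnt, by = c("copy_a", "copy_b")))
    }
  }
  # --- clashes among non-bonded atoms
  excl <- .nt_exclusion(model)
  np <- neighbor_pairs(pos, max(0.6, 2 * clash_dist))
  nt_i <- a$nt[np$i]; nt_j <- a$nt[np$j]
  same <- nt_i == nt_j
  ii <- excl$id[as.character(nt_i)]; jj <- excl$id[as.character(nt_j)]
  bonded <- same | (excl$E[cbind(ii, jj)])
  np <- np[!bonded]
  min_dist <- if (nrow(np)) min(np$d) else NA_real_
  cl <- np[np$d < clash_dist]
  clash_pairs <- data.frame(atom_i = cl$i, atom_j = cl$j,
                            nt_i = a$nt[cl$i], nt_j = a$nt[cl$j], d = cl$d)
  structure(list(hbonds = hb, sticky = sticky, min_dist = min_dist,
                 clash_pairs = clash_pairs,
                 clash_dist = clash_dist, hbond_band = hbond_band),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("validation_report\n")
  if (!is.null(x$hbonds)) {
    cat(sprintf("  H-bond sites: %d, range %.3f-%.3f nm (band %.2f-%.2f)\n",
                nrow(x$hbonds), min(x$hbonds$d), max(x$hbonds$d),
                x$hbond_band[1], x$hbond_band[2]))
  }
  if (!is.null(x$sticky)) {
    cat(sprintf("  sticky interfaces: %d, base pairs per interface: %s\n",
                nrow(x$sticky), paste(unique(x$sticky$n_pairs), collapse = "/")))
  }
  cat(sprintf("  min non-bonded distance: %.3f nm; clashes (< %.2f nm): %d\n",
              x$min_dist, x$clash_dist, nrow(x$clash_pairs)))
  invisible(x)
}

#' Measure ring diameters
#'
#' Outer diameter: twice the maximum radial distance of any atom from the
#' ring (z) axis.  Inner diameter: twice the minimum radial distance of
#' inner-circle duplex-axis points (per-base-pair atom centroids of
#' inner-circle nucleotides) from the axis.
#'
#' @param model A ring [fine_model()].
#' @return list with `outer` and `inner` diameters in nm.
#' @export
measure_ring_diameters <- function(model) {
  a <- model$atoms
  inner_nts <- unique(a$nt[a$role == "inner_circle"])
  if (!length(inner_nts)) {
    abort_dnanma("model has no inner_circle-role atoms", "dnanma_unsupported_structure")
  }
  outer <- 2 * sqrt(max(a$x^2 + a$y^2))
  pr <- model$pairs[model$pairs$nt_a %in% inner_nts &
                      model$pairs$nt_b %in% inner_nts, , drop = FALSE]
  at <- data.table::as.data.table(a)[nt %in% c(pr$nt_a, pr$nt_b)]
  bpid <- stats::setNames(rep(seq_len(nrow(pr)), 2), c(pr$nt_a, pr$nt_b))
  at[, bp_group := bpid[as.character(nt)]]
  ctr <- at[, .(cx = mean(x), cy = mean(y)), by = bp_group]
  inner <- 2 * min(sqrt(ctr$cx^2 + ctr$cy^2))
  list(outer = outer, inner = inner)
}

#' Tile adjacency graph of an assembly
#'
#' @param model An assembled [fine_model()].
#' @return list with `centers` (per-copy centroid matrix) and `interfaces`
#'   (2-column matrix of copy pairs joined by hybridized sticky ends).
#' @export
tile_graph <- function(model) {
  a <- data.table::as.data.table(model$atoms)
  ctr <- a[, .(x = mean(x), y = mean(y), z = mean(z)), by = copy][order(copy)]
  copy_of <- stats::setNames(a$copy, as.character(a$nt))
  ca <- copy_of[as.character(model$pairs$nt_a)]
  cb <- copy_of[as.character(model$pairs$nt_b)]
  cross <- ca != cb
  ifc <- unique(data.frame(a = pmin(ca[cross], cb[cross]),
                           b = pmax(ca[cross], cb[cross])))
  list(centers = as.matrix(ctr[, .(x, y, z)]), interfaces = as.matrix(ifc))
}

#' Polyhedral topology of a tile assembly
#'
#' Recovers vertices, edges and faces of the tile adjacency graph embedded
#' on its sphere (faces traced through the rotation system induced by the
#' embedding), and checks the Euler characteristic V - E + F = 2.
#'
#' @param centers q x 3 matrix of tile center positions.
#' @param interfaces 2-column matrix of tile index pairs.
#' @return list with `vertices`, `edges`, `faces`, `faces_by_size` (named
#'   integer vector keyed by cycle length).
#' @export
assembly_topology <- function(centers, interfaces) {
  q <- nrow(centers)
  g <- igraph::graph_from_edgelist(as.matrix(interfaces), directed = FALSE)
  g <- igraph::simplify(g)
  if (igraph::vcount(g) < q) {
    g <- igraph::add_vertices(g, q - igraph::vcount(g))
  }
  if (!igraph::is_connected(g)) {
    abort_dnanma("tile adjacency graph is not connected", "dnanma_topology_error")
  }
  nE <- igraph::ecount(g)
  ctr <- colMeans(centers)
  # cyclic neighbor order around each vertex, viewed from outside
  nbrs <- lapply(seq_len(q), function(v) {
    nb <- as.integer(igraph::neighbors(g, v))
    u <- centers[v, ] - ctr
    nu <- .unit(if (sqrt(sum(u^2)) > 1e-9) u else c(0, 0, 1))
    e1 <- c(1, 0, 0); if (abs(sum(e1 * nu)) > 0.9) e1 <- c(0, 1, 0)
    e1 <- .unit(e1 - sum(e1 * nu) * nu)
    e2 <- c(nu[2] * e1[3] - nu[3] * e1[2], nu[3] * e1[1] - nu[1] * e1[3],
            nu[1] * e1[2] - nu[2] * e1[1])
    d <- centers[nb, , drop = FALSE] - matrix(centers[v, ], length(nb), 3, byrow = TRUE)
    ang <- atan2(d %*% e2, d %*% e1)
    nb[order(ang)]
  })
  # face tracing: after arriving at v from u, leave along the neighbor
  # preceding u in v's cyclic order
  visited <- new.env(parent = emptyenv())
  faces <- list()
  for (v0 in seq_len(q)) for (w0 in nbrs[[v0]]) {
    ekey <- paste(v0, w0)
    if (exists(ekey, envir = visited)) next
    face <- integer(0)
    u <- v0; v <- w0
    repeat {
      assign(paste(u, v), TRUE, envir = visited)
      face <- c(face, u)
      nb <- nbrs[[v]]
      pos <- match(u, nb)
      w <- nb[(pos - 2) %% length(nb) + 1]
      u <- v; v <- w
      if (u == v0 && v == w0) break
      if (length(face) > 10 * q) {
        abort_dnanma("face tracing failed (non-spherical embedding)",
                     "dnanma_topology_error")
      }
    }
    faces[[length(faces) + 1]] <- face
  }
  nF <- length(faces)
  if (q - nE + nF != 2) {
    abort_dnanma(sprintf("Euler check failed: V=%d E=%d F=%d", q, nE, nF),
                 "dnanma_topology_error")
  }
  sizes <- table(lengths(faces))
  list(vertices = as.integer(q), edges = as.integer(nE), faces = as.integer(nF),
       faces_by_size = stats::setNames(as.integer(sizes), names(sizes)))
}
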