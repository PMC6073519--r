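# Tile extraction and symmetric assembly.

#' Build a single unit tile
#'
#' Constructs the copy-1 tile of a design, positioned so that applying the
#' design's symmetry group reproduces the full assembly (ring tiles occupy
#' their 30-degree sector; the curved three-point-star tile sits at its cage
#' vertex).  Sticky-end overhang nucleotides are present but unpaired.
#'
#' @param design A tile design (`ring_design` or `star_design`).
#' @param ... Passed to methods.
#' @return A [fine_model()] of the tile.
#' @export
build_tile <- function(design, ...) UseMethod("build_tile")

#' @export
build_tile.ring_design <- function(design, ...) {
  full <- .ring_full(design)
  .extract_copy(full, 1L, meta = list(kind = "ring_tile", design = design))
}

# subset one tile copy, keeping intra-copy pairs and links
.extract_copy <- function(model, copy_id, meta) {
  atoms <- model$atoms[model$atoms$copy == copy_id, , drop = FALSE]
  keep_nt <- unique(atoms$nt)
  pr <- model$pairs[model$pairs$nt_a %in% keep_nt & model$pairs$nt_b %in% keep_nt, , drop = FALSE]
  ln <- model$links[model$links$nt_a %in% keep_nt & model$links$nt_b %in% keep_nt, , drop = FALSE]
  meta$parent <- model$meta$kind
  fine_model(atoms, pr, ln, meta = meta)
}

#' Assemble tile copies under a symmetry group
#'
#' Applies every rotation of `group` to the tile (copy i is rotation i
#' applied to copy 1), then hybridizes complementary sticky-end overhangs
#' that come to lie within pairing distance of each other.
#'
#' @param tile A [fine_model()] tile whose atoms carry copy index 1.
#' @param group A `symmetry_group`.
#' @param pair_max_dist Maximum primary-site distance (nm) for two
#'   complementary overhang bases to hybridize.
#' @param strict Raise an assembly error when an overhang that evidently
#'   faces a complementary partner (within `3 * pair_max_dist`) fails to
#'   reach pairing distance.
#' @return A [fine_model()] of the assembly with per-atom tile copy indices
#'   and hybridized sticky-end pairs.
#' @export
assemble <- function(tile, group, pair_max_dist = dnanma_defaults()$pair_max_dist,
                     strict = TRUE) {
  q <- group$order
  at <- tile$atoms
  nt_span <- max(at$nt) + 1L
  parts <- vector("list", q)
  xyz <- as.matrix(at[, c("x", "y", "z")])
  for (i in seq_len(q)) {
    ai <- at
    pos <- xyz %*% t(group$rotations[[i]])
    ai$x <- pos[, 1]; ai$y <- pos[, 2]; ai$z <- pos[, 3]
    ai$copy <- i
    if (q > 1) {
      off <- (i - 1L) * nt_span
      ai$nt <- ai$nt + off
      ai$strand <- paste0(ai$strand, ".c", i)
      pi_ <- tile$pairs; pi_$nt_a <- pi_$nt_a + off; pi_$nt_b <- pi_$nt_b + off
      li <- tile$links; li$nt_a <- li$nt_a + off; li$nt_b <- li$nt_b + off
    } else {
      pi_ <- tile$pairs; li <- tile$links
    }
    parts[[i]] <- list(atoms = ai, pairs = pi_, links = li)
  }
  meta <- tile$meta
  meta$kind <- sub("_tile$", "", meta$kind %||% "assembly")
  meta$group_name <- group$name
  meta$q <- q
  model <- .bind_models(parts, meta = meta)
  if (q > 1) model <- hybridize_sticky(model, pair_max_dist, strict = strict)
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Hybridize sticky-end overhangs by proximity
#'
#' Pairs unpaired sticky-flagged nucleotides whose Watson-Crick primary
#' sites are complementary, belong to different tile copies, and lie within
#' `pair_max_dist` of each other (greedy nearest-first matching).
#'
#' @inheritParams assemble
#' @param model A [fine_model()] assembly.
#' @return The model with hybridized pairs appended.
#' @export
hybridize_sticky <- function(model, pair_max_dist = dnanma_defaults()$pair_max_dist,
                             strict = TRUE) {
  a <- model$atoms
  paired <- c(model$pairs$nt_a, model$pairs$nt_b)
  prim <- a[a$sticky & !(a$nt %in% paired) &
              ((a$base %in% PURINES & a$name == "N1") |
                 (a$base %in% PYRIMIDINES & a$name == "N3")), , drop = FALSE]
  if (!nrow(prim)) return(model)
  xyz <- as.matrix(prim[, c("x", "y", "z")])
  cand <- neighbor_pairs(xyz, 3 * pair_max_dist)
  if (nrow(cand)) {
    ok <- COMPLEMENT[prim$base[cand$i]] == prim$base[cand$j] &
      prim$copy[cand$i] != prim$copy[cand$j]
    cand <- cand[ok]
  }
  new_a <- new_b <- integer(0)
  used <- logical(nrow(prim))
  cand <- cand[order(cand$d)]
  far <- list()
  for (r in seq_len(nrow(cand))) {
    i <- cand$i[r]; j <- cand$j[r]
    if (used[i] || used[j]) next
    if (cand$d[r] <= pair_max_dist) {
      used[i] <- used[j] <- TRUE
      new_a <- c(new_a, prim$nt[i]); new_b <- c(new_b, prim$nt[j])
    } else {
      far[[length(far) + 1]] <- sprintf(
        "copies %d/%d at %.2f nm", prim$copy[i], prim$copy[j], cand$d[r])
    }
  }
  if (strict && length(far)) {
    abort_dnanma(
      paste0("sticky ends fail to reach pairing distance at interfaces: ",
             paste(unique(unlist(far)), collapse = "; ")),
      "dnanma_assembly_error")
  }
  model$pairs <- rbind(model$pairs, data.frame(nt_a = new_a, nt_b = new_b))
  model
}

#' Build a complete ring assembly
#'
#' @param design A [ring_design()].
#' @return A [fine_model()] of the 12-tile (by default) ring.
#' @export
build_ring <- function(design) {
  if (is.character(design)) design <- ring_design(design)
  assemble(build_tile(design), cyclic_group(design$n_tiles))
}
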