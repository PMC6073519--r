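# The fine (atom-level) structure model.
#
# A `fine_model` bundles the atom table of a built structure with its
# nucleotide table, designed Watson-Crick pairs, and designed inter-segment
# junction links.  It is the input to validation and coarse-graining.

#' Construct a fine model
#'
#' @param atoms data.frame with columns x, y, z (nm), element, name, mass
#'   (amu), nt (global nucleotide id), strand (strand fragment id), ord
#'   (position along the strand, ascending 5' to 3'), base, copy (tile copy
#'   index), role (segment role), sticky (logical), rep (representative-atom
#'   flag), bead (bead id or NA), glyc (glycosidic-atom flag).
#' @param pairs data.frame with columns nt_a, nt_b of Watson-Crick paired
#'   nucleotides (designed or hybridized).
#' @param links data.frame with columns nt_a, nt_b of designed junction
#'   links (strand crossovers between segments).
#' @param meta named list of builder metadata.
#' @return Object of class `fine_model`.
#' @export
fine_model <- function(atoms, pairs = NULL, links = NULL, meta = list()) {
  if (is.null(pairs)) pairs <- data.frame(nt_a = integer(), nt_b = integer())
  if (is.null(links)) links <- data.frame(nt_a = integer(), nt_b = integer())
  stopifnot(all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
  structure(list(atoms = atoms, pairs = pairs, links = links, meta = meta),
            class = "fine_model")
}

#' @export
print.fine_model <- function(x, ...) {
  a <- x$atoms
  cat("fine_model:", nrow(a), "atoms,", length(unique(a$nt)), "nucleotides,",
      length(unique(a$strand)), "strand fragments,",
      length(unique(a$copy)), "tile copies\n")
  cat("  roles:", paste(sort(unique(a$role)), collapse = ", "), "\n")
  cat("  pairs:", nrow(x$pairs), " links:", nrow(x$links), "\n")
  if (!is.null(x$meta$kind)) cat("  kind:", x$meta$kind, "\n")
  invisible(x)
}

# per-nucleotide summary table
nt_table <- function(model) {
  a <- data.table::as.data.table(model$atoms)
  a[, .(strand = strand[1], ord = ord[1], base = base[1], copy = copy[1],
        role = role[1], sticky = sticky[1], has_p = any(name == "P")),
    by = nt][order(nt)]
}

# combine several atom/pair/link bundles, keeping nt ids already globalized
.bind_models <- function(parts, meta = list()) {
  fine_model(
    atoms = do.call(rbind, lapply(parts, `[[`, "atoms")),
    pairs = do.call(rbind, lapply(parts, `[[`, "pairs")),
    links = do.call(rbind, lapply(parts, `[[`, "links")),
    meta = meta
  )
}

#' Total mass of a model
#' @param model fine_model or cg_model.
#' @return Total mass in amu.
#' @export
total_mass <- function(model) {
  if (inherits(model, "fine_model")) sum(model$atoms$mass) else sum(model$beads$mass)
}
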