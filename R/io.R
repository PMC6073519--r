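# File formats: PDB structures, NMD-style mode files, spring/mode/label
# CSV tables, and YAML design configuration.

.CHAIN_IDS <- c(LETTERS, letters, 0:9)

# map an arbitrary strand id vector to single-character chain ids (cycled)
.chain_of <- function(strand) {
  f <- as.integer(factor(strand, levels = unique(strand)))
  .CHAIN_IDS[(f - 1) %% length(.CHAIN_IDS) + 1]
}

#' Write a structure to PDB
#'
#' Fine models are written atom by atom (one chain per strand copy,
#' residue numbers from nucleotide ids); coarse models write one atom per
#' bead with the lumped mass in the B-factor column.  Coordinates are
#' converted from nm to Angstrom.
#'
#' @param x A [fine_model()], [cg_model()], or a data.frame as returned by
#'   [read_pdb()].
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_pdb <- function(x, path) {
  if (inherits(x, "fine_model")) {
    a <- x$atoms
    df <- data.frame(
      name = a$name, resname = paste0("D", a$base), chain = .chain_of(a$strand),
      resid = a$nt %% 10000, x = a$x, y = a$y, z = a$z,
      bfac = 0, element = a$element, stringsAsFactors = FALSE)
  } else if (inherits(x, "cg_model")) {
    b <- x$beads
    df <- data.frame(
      name = b$bead, resname = paste0("D", b$base), chain = .chain_of(b$strand),
      resid = b$nt %% 10000, x = b$x, y = b$y, z = b$z,
      bfac = b$mass, element = substr(b$bead, 1, 1), stringsAsFactors = FALSE)
  } else {
    df <- x
  }
  if (nrow(df) > 99999) {
    warning("more than 99999 atoms: PDB serial numbers wrap")
  }
  name4 <- ifelse(nchar(df$name) < 4, sprintf(" %-3s", df$name),
                  substr(df$name, 1, 4))
  lines <- sprintf(
    "ATOM  %5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    (seq_len(nrow(df)) - 1) %% 99999 + 1, name4, df$resname, df$chain,
    df$resid, df$x * 10, df$y * 10, df$z * 10, 1, df$bfac, df$element)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Read a PDB file written by [write_pdb()]
#'
#' @param path PDB file.
#' @return data.frame with name, resname, chain, resid, x, y, z (nm),
#'   bfac, element.
#' @export
read_pdb <- function(path) {
  ln <- readLines(path)
  ln <- ln[startsWith(ln, "ATOM")]
  data.frame(
    name = trimws(substr(ln, 13, 16)),
    resname = trimws(substr(ln, 18, 20)),
    chain = substr(ln, 22, 22),
    resid = as.integer(substr(ln, 23, 26)),
    x = as.numeric(substr(ln, 31, 38)) / 10,
    y = as.numeric(substr(ln, 39, 46)) / 10,
    z = as.numeric(substr(ln, 47, 54)) / 10,
    bfac = as.numeric(substr(ln, 61, 66)),
    element = trimws(substr(ln, 77, 78)),
    stringsAsFactors = FALSE
  )
}

#' Write the spring table as CSV
#'
#' @param cg A [cg_model()].
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_springs_csv <- function(cg, path) {
  utils::write.csv(cg$springs[, c("i", "j", "type", "k", "rest")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a spring table CSV
#' @param path CSV file from [write_springs_csv()].
#' @return data.frame of springs.
#' @export
read_springs_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write mode frequencies and labels as CSV
#'
#' @param modes A `mode_set`.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_modes_csv <- function(modes, path) {
  n <- length(modes$lambda)
  z <- modes$zero_modes
  lab <- rep(NA_character_, n)
  if (!is.null(modes$labels)) {
    lab[z + seq_along(modes$labels)] <- modes$labels
  }
  df <- data.frame(
    index = seq_len(n),
    nonrigid_index = ifelse(seq_len(n) > z, seq_len(n) - z, NA),
    lambda = modes$lambda, omega_radps = modes$omega_radps,
    freq_cm1 = modes$freq_cm1, rigid = seq_len(n) <= z, label = lab)
  utils::write.csv(format(df, digits = 17, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write modes in NMD format
#'
#' Plain-text NMD mode file (coordinates in Angstrom plus per-mode scaled
#' eigenvectors) consumable by common structure viewers.
#'
#' @param modes A `mode_set`.
#' @param cg The matching [cg_model()].
#' @param path Output file.
#' @param n_modes How many modes to write (default: all computed).
#' @return The path, invisibly.
#' @export
write_modes_nmd <- function(modes, cg, path, n_modes = ncol(modes$vectors)) {
  b <- cg$beads
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("nmd generated by dnanma", con)
  writeLines(paste("names", paste(b$bead, collapse = " ")), con)
  writeLines(paste("resids", paste(b$nt, collapse = " ")), con)
  writeLines(paste("coordinates",
                   paste(sprintf("%.3f", 10 * as.numeric(t(as.matrix(
                     b[, c("x", "y", "z")])))), collapse = " ")), con)
  for (k in seq_len(min(n_modes, ncol(modes$vectors)))) {
    writeLines(paste("mode", k, sprintf("%.6g", modes$lambda[k]),
                     paste(sprintf("%.6g", modes$vectors[, k]), collapse = " ")),
               con)
  }
  invisible(path)
}

#' Export mode labels in the summary-table layout
#'
#' Combines labeled mode sets of several structures into the mode-number by
#' structure label table.
#'
#' @param mode_sets Named list of labeled `mode_set` objects.
#' @param n_modes Number of non-rigid modes per column (default 10).
#' @return data.frame with `mode` plus one column per structure.
#' @export
mode_label_table <- function(mode_sets, n_modes = 10) {
  out <- data.frame(mode = seq_len(n_modes))
  for (nm in names(mode_sets)) {
    lab <- mode_sets[[nm]]$labels
    out[[nm]] <- c(lab, rep(NA, n_modes))[seq_len(n_modes)]
  }
  out
}

#' Build a design object from a configuration list or YAML file
#'
#' Recognized forms: a character name ("r1o", "r1c", "r2o", "r2c",
#' "buckyball", "tile", "mini_ball"), or a list with a `design` entry of
#' that name plus optional parameter overrides passed to [ring_design()] /
#' [star_design()].
#'
#' @param config File path to a YAML config or a named list.
#' @return A tile design object.
#' @export
design_from_config <- function(config) {
  if (is.character(config) && length(config) == 1 && file.exists(config)) {
    config <- yaml::read_yaml(config)
  }
  if (is.character(config)) config <- list(design = config)
  nm <- config$design %||% "r1c"
  pars <- config[setdiff(names(config),
                         c("design", "method", "modes", "cutoff", "out_dir",
                           "seed", "n_label", "flat"))]
  if (nm %in% c("r1o", "r1c", "r2o", "r2c")) {
    do.call(ring_design, c(list(variant = nm), pars))
  } else if (nm %in% c("buckyball", "mini_ball", "tile")) {
    do.call(star_design, c(list(kind = nm), pars))
  } else {
    abort_dnanma(paste("unknown design", nm), "dnanma_invalid_input")
  }
}
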