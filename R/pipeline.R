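# End-to-end pipeline: build -> validate -> coarse-grain -> solve ->
# classify -> export, with structured stage logging and byte-stable
# outputs for a given configuration.

#' Run the full analysis pipeline
#'
#' @param config Named list (or YAML file path) with entries:
#'   \describe{
#'     \item{design}{design name ("r1o", "r1c", "r2o", "r2c", "buckyball",
#'       "tile", "mini_ball") plus optional design parameter overrides.}
#'     \item{method}{"nma" (full model) or "scenm" (symmetry-reduced;
#'       cage assemblies).}
#'     \item{modes}{number of modes to solve for (default 16).}
#'     \item{cutoff}{van der Waals cutoff in nm (default 0.8).}
#'     \item{n_label}{non-rigid modes to label (default 10).}
#'     \item{seed}{seed for the iterative eigensolver start (default 1).}
#'     \item{out_dir}{output directory; when NULL nothing is written.}
#'   }
#' @return A result bundle: the built model, validation report, coarse
#'   model, mode set (labeled), tile-graph topology for cage assemblies,
#'   the config hash, stage log, and paths of files written.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(
    list(design = "r1c", method = "nma", modes = 16, cutoff = dnanma_defaults()$cutoff,
         n_label = 10, seed = 1L, out_dir = NULL, flat = NULL),
    config)
  hcfg <- cfg[setdiff(sort(names(cfg)), "out_dir")]   # hash the computation
  hash <- rlang::hash(hcfg)
  log <- character(0)
  say <- function(...) {
    log <<- c(log, sprintf(...))
    message(log[length(log)])
  }
  design <- design_from_config(cfg)
  dname <- cfg$design
  say("stage build: design %s", dname)
  structure_class <- if (inherits(design, "ring_design")) "ring"
    else if (design$kind == "tile" || isTRUE(cfg$flat)) "tile" else "buckyball"
  model <- switch(structure_class,
    ring = build_ring(design),
    tile = build_3ps_tile(design),
    buckyball = if (design$kind == "mini_ball") build_mini_ball(design)
                else build_buckyball(design))
  say("stage build: %d atoms, %d nucleotides, %d tile copies",
      nrow(model$atoms), length(unique(model$atoms$nt)),
      length(unique(model$atoms$copy)))
  report <- validate_structure(model)
  say("stage validate: %d H-bond sites, %d clashes, min non-bonded %.3f nm",
      if (is.null(report$hbonds)) 0L else nrow(report$hbonds),
      nrow(report$clash_pairs), report$min_dist)
  cg <- coarse_grain(model, cutoff = cfg$cutoff)
  say("stage coarse_grain: %d beads, %d springs (cutoff %.2f nm)",
      nrow(cg$beads), nrow(cg$springs), cfg$cutoff)
  q <- length(unique(cg$beads$copy))
  say("stage coarse_grain: beads = %d copies x %d per tile", q, nrow(cg$beads) %/% q)
  topo <- NULL
  if (structure_class == "buckyball") {
    tg <- tile_graph(model)
    topo <- assembly_topology(tg$centers, tg$interfaces)
    say("stage topology: V=%d E=%d F=%d", topo$vertices, topo$edges, topo$faces)
  }
  group <- NULL
  if (cfg$method == "scenm") {
    group <- if (inherits(design, "ring_design")) cyclic_group(design$n_tiles)
      else .poly_geometry(design$kind)$group
    say("stage scenm: group %s (q=%d), reduced order %d",
        group$name, group$order, 3 * nrow(cg$beads) %/% group$order)
    modes <- scenm_modes(cg, group, n_modes = cfg$modes)
    say("stage scenm: asymmetry residual %.2e, max eigen residual %.2e",
        modes$asymmetry, max(modes$residuals))
  } else {
    modes <- solve_modes(cg, n_modes = cfg$modes, seed = cfg$seed)
    say("stage nma: %d modes, %d rigid", length(modes$lambda), modes$zero_modes)
  }
  modes <- label_modes(modes, cg, structure_class, n_label = cfg$n_label)
  say("stage classify: %s", paste(modes$labels, collapse = " "))
  files <- character(0)
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    fp <- function(f) file.path(cfg$out_dir, f)
    if (nrow(model$atoms) <= 99999) {
      write_pdb(model, fp("structure.pdb")); files <- c(files, fp("structure.pdb"))
    }
    write_pdb(cg, fp("cg.pdb"))
    write_springs_csv(cg, fp("springs.csv"))
    write_modes_csv(modes, fp("modes.csv"))
    write_modes_nmd(modes, cg, fp("modes.nmd"))
    utils::write.csv(mode_label_table(stats::setNames(list(modes), dname),
                                      n_modes = cfg$n_label),
                     fp("labels.csv"), row.names = FALSE, quote = FALSE)
    cfg_out <- cfg; cfg_out$config_hash <- hash
    yaml::write_yaml(cfg_out[sort(names(cfg_out))], fp("config.yaml"))
    writeLines(c(sprintf("config_hash %s", hash), log), fp("log.txt"))
    files <- c(files, fp("cg.pdb"), fp("springs.csv"), fp("modes.csv"),
               fp("modes.nmd"), fp("labels.csv"), fp("config.yaml"), fp("log.txt"))
  }
  invisible(list(
    config = cfg, config_hash = hash, design = design, model = model,
    report = report, cg = cg, modes = modes, topology = topo,
    structure_class = structure_class, log = log, files = files))
}
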