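#' Resolve a run configuration
#'
#' Central configuration for the analysis stages. Defaults carry the study
#' conditions: GNM cutoff 7.3 A, ANM cutoff 13 A, 40 modes for the
#' cross-correlation map. Any field can be overridden; precedence is
#' overrides > config file > defaults. The resolved configuration is
#' echoed to `config.yaml` in the output directory by every run.
#'
#' @param ... field overrides (see Details).
#' @param file optional YAML config file whose values sit between the
#'   defaults and `...`.
#' @return a list of class `run_config` with fields `input` (PDB path) or
#'   `synthetic` (argument list for [synthetic_structure()]), `chain`,
#'   `model`, `gnm_cutoff`, `anm_cutoff`, `n_modes_correlation`,
#'   `zero_tol`, `gamma`, `kT_scale`, `domains` (range list for
#'   [assign_domains()]), `hinge_window`, `hinge_prominence`, `out_dir`,
#'   `seed`, `make_plots`.
#' @export
run_config <- function(..., file = NULL) {
  cfg <- list(
    input = NULL, synthetic = NULL, chain = "A", model = 1L,
    gnm_cutoff = 7.3, anm_cutoff = 13, n_modes_correlation = 40L,
    zero_tol = 1e-8, gamma = 1, kT_scale = 1,
    domains = NULL, hinge_window = 5L, hinge_prominence = 0.05,
    out_dir = "enmodes_out", seed = 1L, make_plots = FALSE)
  if (!is.null(file)) {
    from_file <- yaml::read_yaml(file)
    bad <- setdiff(names(from_file), names(cfg))
    if (length(bad) > 0L)
      stop("unknown config field(s): ", paste(bad, collapse = ", "))
    cfg[names(from_file)] <- from_file
  }
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad) > 0L)
    stop("unknown config field(s): ", paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "run_config")
}

# resolve the input structure named by a config
.load_input <- function(cfg, which = "input") {
  src <- cfg[[which]]
  if (!is.null(src)) {
    if (!file.exists(src)) stop("input file not found: ", src)
    nodes <- parse_structure(src, chain = cfg$chain, model = cfg$model)
  } else if (!is.null(cfg$synthetic)) {
    args <- cfg$synthetic
    if (is.null(args$seed)) args$seed <- cfg$seed
    nodes <- do.call(synthetic_structure, args)
  } else {
    stop("config names neither an input file nor a synthetic spec")
  }
  reindex_contiguous(nodes)
}

.annotation_for <- function(cfg, nodes) {
  if (!is.null(cfg$domains)) return(assign_domains(nodes, cfg$domains))
  ann <- attr(nodes, "annotation")
  if (!is.null(ann)) return(ann)
  NULL
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# echo config + hash all outputs so identical reruns are verifiable
.finish_run <- function(cfg, out, files) {
  cfg_path <- file.path(out, "config.yaml")
  plain <- unclass(cfg)
  plain <- plain[!vapply(plain, is.null, TRUE)]
  yaml::write_yaml(plain, cfg_path)
  files <- c(files, cfg_path)
  hashes <- as.list(tools::md5sum(files))
  names(hashes) <- basename(names(hashes))
  manifest <- list(package = "enmodes",
                   version = as.character(utils::packageVersion("enmodes")),
                   config = plain, outputs = hashes)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(files = files, manifest = manifest))
}

#' Run the GNM stage
#'
#' Loads or generates the input structure, builds and decomposes the
#' Kirchhoff matrix, and writes: the node table, contact statistics, the
#' eigenvalue spectrum, mean-square fluctuations over all modes, the
#' slowest-mode normalized profile with per-segment statistics, and the
#' hinge report. A `manifest.json` with the resolved configuration and
#' md5 hashes of every output makes reruns verifiable.
#'
#' @param cfg a [run_config()].
#' @return (invisibly) list with the computed objects and output paths.
#' @export
run_gnm <- function(cfg = run_config()) {
  out <- cfg$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  nodes <- .load_input(cfg)
  params <- enm_params(cutoff = cfg$gnm_cutoff, gamma = cfg$gamma,
                       kT_scale = cfg$kT_scale)
  k <- build_kirchhoff(nodes, params)
  spec <- gnm_decompose(k, zero_tol = cfg$zero_tol, params = params)
  ann <- .annotation_for(cfg, nodes)
  prof <- slow_mode_profile(spec, ann, params)
  hinges <- find_hinges(prof$profile, window = cfg$hinge_window,
                        prominence = cfg$hinge_prominence)
  flus <- msf(spec, "all", params)

  files <- c(
    write_node_table(nodes, file.path(out, "nodes.tsv")),
    .write_tsv(data.frame(n_nodes = nodes$n, cutoff = k$cutoff_used,
                          contacts = k$contact_count,
                          n_zero_modes = spec$n_zero_modes),
               file.path(out, "kirchhoff_stats.tsv")),
    .write_tsv(data.frame(mode = seq_along(spec$values) - spec$n_zero_modes,
                          eigenvalue = spec$values),
               file.path(out, "gnm_spectrum.tsv")),
    .write_tsv(data.frame(node_index = nodes$node, resSeq = nodes$resno,
                          value = flus, normalized_value = flus / sum(flus)),
               file.path(out, "msf.tsv")),
    .write_tsv(data.frame(node_index = nodes$node, resSeq = nodes$resno,
                          value = mode_fluctuation(spec, 1, params)$msf,
                          normalized_value = prof$profile),
               file.path(out, "slow_mode_profile.tsv")),
    .write_tsv(prof$segments, file.path(out, "segment_stats.tsv")),
    .write_tsv(data.frame(hinge_node = hinges$hinges),
               file.path(out, "hinges.tsv")))
  if (isTRUE(cfg$make_plots))
    files <- c(files, plot_profile(prof$profile, ann, hinges$hinges,
                                   file.path(out, "slow_mode_profile.png")))
  fin <- .finish_run(cfg, out, files)
  invisible(list(nodes = nodes, kirchhoff = k, spectrum = spec,
                 profile = prof, hinges = hinges, msf = flus,
                 files = fin$files))
}

#' Run the cross-correlation stage
#'
#' GNM decomposition followed by the normalized cross-correlation map over
#' the configured mode range (default: first 40 non-rigid modes), written
#' as a TSV matrix, with the per-domain block means when an annotation is
#' available, and optionally a heat-map PNG.
#'
#' @param cfg a [run_config()].
#' @return (invisibly) list with the map and output paths.
#' @export
run_crosscorr <- function(cfg = run_config()) {
  out <- cfg$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  nodes <- .load_input(cfg)
  params <- enm_params(cutoff = cfg$gnm_cutoff, gamma = cfg$gamma,
                       kT_scale = cfg$kT_scale)
  spec <- gnm_decompose(build_kirchhoff(nodes, params),
                        zero_tol = cfg$zero_tol, params = params)
  cc <- cross_correlation(spec, count = cfg$n_modes_correlation)
  files <- character(0)
  cc_path <- file.path(out, "cross_correlation.tsv")
  utils::write.table(round(cc$matrix, 8), cc_path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  files <- c(files, cc_path)
  ann <- .annotation_for(cfg, nodes)
  blocks <- NULL
  if (!is.null(ann)) {
    blocks <- block_correlation(cc, ann)
    bp <- file.path(out, "block_correlation.tsv")
    utils::write.table(round(blocks, 8), bp, sep = "\t", quote = FALSE,
                       row.names = TRUE, col.names = NA)
    files <- c(files, bp)
  }
  if (isTRUE(cfg$make_plots))
    files <- c(files, plot_correlation_map(
      cc, file.path(out, "cross_correlation.png")))
  fin <- .finish_run(cfg, out, files)
  invisible(list(nodes = nodes, map = cc, blocks = blocks,
                 files = fin$files))
}

#' Run the ANM stage
#'
#' Builds and decomposes the anisotropic Hessian at the configured ANM
#' cutoff and writes the spectrum, per-node magnitude tables for the
#' slowest modes, and an NMD file for mode viewers.
#'
#' @param cfg a [run_config()].
#' @param n_modes how many slowest non-rigid modes to export.
#' @return (invisibly) list with the spectrum and output paths.
#' @export
run_anm <- function(cfg = run_config(), n_modes = 2L) {
  out <- cfg$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  nodes <- .load_input(cfg)
  params <- enm_params(cutoff = cfg$anm_cutoff, gamma = cfg$gamma,
                       kT_scale = cfg$kT_scale)
  h <- build_hessian(nodes, params)
  spec <- anm_decompose(h, zero_tol = cfg$zero_tol)
  avail <- length(spec$values) - spec$n_zero_modes
  n_modes <- min(as.integer(n_modes), avail)
  files <- c(
    .write_tsv(data.frame(mode = seq_along(spec$values) - spec$n_zero_modes,
                          eigenvalue = spec$values),
               file.path(out, "anm_spectrum.tsv")))
  for (m in seq_len(n_modes)) {
    mv <- mode_vectors(spec, m)
    files <- c(files, .write_tsv(
      data.frame(node_index = nodes$node, resSeq = nodes$resno,
                 dx = mv$vectors[, 1], dy = mv$vectors[, 2],
                 dz = mv$vectors[, 3], magnitude = mv$magnitude),
      file.path(out, sprintf("anm_mode_%d.tsv", m))))
  }
  nmd <- write_nmd(nodes, spec, modes = seq_len(n_modes),
                   path = file.path(out, "anm_modes.nmd"))
  files <- c(files, nmd)
  fin <- .finish_run(cfg, out, files)
  invisible(list(nodes = nodes, hessian = h, spectrum = spec,
                 files = fin$files))
}

#' Run the superposition stage
#'
#' Superposes a mobile structure onto a reference (trimmed-core fit by
#' default), writes the per-residue deviation table, the transform, and
#' the transformed mobile structure as a PDB with deviations in the
#' B-factor column for color-by-deviation rendering.
#'
#' @param cfg a [run_config()]; `input` names the reference structure.
#' @param mov_input path to the mobile structure (PDB); alternatively a
#'   [node_set()] passed directly.
#' @param fit passed to [superpose_nodes()].
#' @return (invisibly) the superposition result plus output paths.
#' @export
run_superpose <- function(cfg = run_config(), mov_input, fit = "trimmed") {
  out <- cfg$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  ref <- .load_input(cfg)
  mov <- if (inherits(mov_input, "node_set")) mov_input else {
    if (!file.exists(mov_input)) stop("input file not found: ", mov_input)
    reindex_contiguous(parse_structure(mov_input, chain = cfg$chain,
                                       model = cfg$model))
  }
  res <- superpose_nodes(ref, mov, fit = fit)
  p <- res$pairs
  dev_tab <- data.frame(
    ref_node = p[, "ref"], mov_node = p[, "mov"],
    resSeq = ref$resno[p[, "ref"] + 1L],
    deviation = res$per_residue_deviation,
    in_fit = seq_len(nrow(p)) %in% res$fit_selection)
  # deviation written into B-factors of the transformed mobile structure
  moved <- mov
  moved$xyz <- sweep(mov$xyz %*% res$rotation, 2, res$translation, "+")
  bf <- numeric(mov$n)
  bf[p[, "mov"] + 1L] <- res$per_residue_deviation
  files <- c(
    .write_tsv(dev_tab, file.path(out, "per_residue_deviation.tsv")),
    .write_tsv(data.frame(rmsd = res$rmsd,
                          n_fit = length(res$fit_selection),
                          n_pairs = nrow(p)),
               file.path(out, "superposition_stats.tsv")),
    write_pdb_ca(moved, file.path(out, "mov_superposed.pdb"), bfactor = bf))
  fin <- .finish_run(cfg, out, files)
  res$files <- fin$files
  invisible(res)
}
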