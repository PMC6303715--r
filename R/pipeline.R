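# Three-stage reproducible workflow: simulate -> harmonize -> stats.
# Each stage writes its artifacts plus a machine-readable JSON summary; a
# single global seed drives every stochastic step, and the configuration is
# serialized verbatim into the output directory.

write_json_summary <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Simulation stage: emit synthetic datasets to disk
#'
#' Runs [emit_datasets()] and writes one Genepop file (+ metadata sidecar)
#' per dataset, the replicate-pair table, deme- and location-level distance
#' matrices, the truth-ledger tables, and a JSON stage summary.
#'
#' @param config a [sim_config()] (or a list of its arguments).
#' @param out_dir output directory, created if needed.
#' @return the [emit_datasets()] result, invisibly.
#' @export
run_simulate <- function(config, out_dir) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- emit_datasets(config)
  for (d in names(sim$panels))
    write_panel(sim$panels[[d]], file.path(out_dir, paste0(d, ".gen")),
                "genepop")
  utils::write.csv(sim$pairs, file.path(out_dir, "pairs.csv"),
                   row.names = FALSE, quote = FALSE)
  write_distance_matrix(sim$truth$deme_distances,
                        file.path(out_dir, "deme_distances.csv"))
  write_distance_matrix(sim$truth$location_distances,
                        file.path(out_dir, "location_distances.csv"))
  write_truth_ledger(sim$truth, file.path(out_dir, "truth"))
  yaml::write_yaml(unclass(config), file.path(out_dir, "sim_config.yaml"))
  write_json_summary(list(
    stage = "simulate", seed = config$seed,
    n_datasets = config$n_datasets,
    n_core_loci = ncol(sim$truth$freqs),
    n_injected_flips = nrow(sim$truth$flips),
    n_replicate_pairs = nrow(sim$pairs)),
    file.path(out_dir, "simulate_summary.json"))
  invisible(sim)
}

#' Harmonization stage: QC, strand correction and merge, to disk
#'
#' Accepts in-memory panels or paths to Genepop/VCF files, runs
#' [run_harmonization()], and writes the merged panel (Genepop + metadata
#' sidecar), the QC ledger, calibration and resolution tables, and a JSON
#' summary with the per-rule counters of the QC flow.
#'
#' @param panels named list of `genotype_panel` objects, or character paths.
#' @param pairs replicate-pair table or CSV path.
#' @param out_dir output directory.
#' @param config a [harmonization_config()].
#' @param format,metadata_paths used when `panels` are file paths.
#' @return the `harmonization_result`, invisibly.
#' @export
run_harmonize <- function(panels, pairs, out_dir,
                          config = harmonization_config(),
                          format = "genepop", metadata_paths = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.character(panels)) {
    if (is.null(metadata_paths)) metadata_paths <- paste0(panels, ".meta.csv")
    panels <- mapply(load_panel, panels, metadata_path = metadata_paths,
                     MoreArgs = list(format = format), SIMPLIFY = FALSE)
    names(panels) <- vapply(panels, function(p) p$samples$dataset[1],
                            character(1))
  }
  if (is.character(pairs))
    pairs <- utils::read.csv(pairs, stringsAsFactors = FALSE,
                             colClasses = "character")
  res <- run_harmonization(panels, pairs, config)
  write_panel(res$panel, file.path(out_dir, "merged.gen"), "genepop")
  write_qc_ledger(res$ledger, file.path(out_dir, "qc_ledger.tsv"))
  cal <- res$calibration
  write_tsv(data.frame(locale = rownames(cal$confidence),
                       cal$confidence, check.names = FALSE),
            file.path(out_dir, "calibration.tsv"))
  write_tsv(res$resolution$table, file.path(out_dir, "resolution.tsv"))
  write_json_summary(c(list(stage = "harmonize"),
                       as.list(res$summary)),
                     file.path(out_dir, "harmonize_summary.json"))
  invisible(res)
}

#' Statistics stage: heterozygosity, FST, IBD and regional contrast
#'
#' Computes per-location heterozygosity summaries, the pairwise multi-locus
#' Weir-Cockerham FST matrix (plus per-locus theta against the first pair),
#' and optionally a Mantel isolation-by-distance test on FST/(1 - FST)
#' versus a supplied distance matrix and a Welch within/between-region FST
#' contrast.
#'
#' @param panel a `genotype_panel` or a Genepop/VCF path.
#' @param out_dir output directory.
#' @param distances optional distance matrix (or CSV path) over the panel's
#'   location codes; enables the Mantel test.
#' @param regions optional named vector mapping locations to regions;
#'   enables the Welch contrast.
#' @param n_permutations,seed Mantel permutation settings.
#' @param format,metadata_path used when `panel` is a file path.
#' @return list with `het`, `fst`, `mantel`, `welch`, invisibly.
#' @export
run_stats <- function(panel, out_dir, distances = NULL, regions = NULL,
                      n_permutations = 9999, seed = 1L,
                      format = "genepop", metadata_path = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.character(panel)) {
    if (is.null(metadata_path)) metadata_path <- paste0(panel, ".meta.csv")
    panel <- load_panel(panel, format, metadata_path)
  }
  hets <- lapply(panel$samples$location_code,
                 function(l) heterozygosity(panel, l))
  het_tab <- data.frame(
    location_code = panel$samples$location_code,
    t(vapply(hets, `[[`, numeric(5), "means")),
    stringsAsFactors = FALSE)
  write_tsv(het_tab, file.path(out_dir, "heterozygosity.tsv"))
  fst <- pairwise_fst(panel)
  utils::write.csv(data.frame(location_code = rownames(fst$theta),
                              fst$theta, check.names = FALSE),
                   file.path(out_dir, "pairwise_fst.csv"),
                   row.names = FALSE, quote = FALSE)
  mant <- NULL
  if (!is.null(distances)) {
    if (is.character(distances)) distances <- read_distance_matrix(distances)
    distances <- distances[rownames(fst$theta), rownames(fst$theta)]
    mant <- mantel_ibd(fst$theta, distances, n_permutations, seed = seed)
  }
  wel <- NULL
  if (!is.null(regions)) wel <- regional_fst_welch(fst$theta, regions)
  report <- list(stage = "stats",
                 mean_Ho = mean(het_tab$Ho), mean_He = mean(het_tab$He),
                 fst_range = range(fst$theta[upper.tri(fst$theta)]))
  if (!is.null(mant))
    report$mantel <- list(r = mant$r, p = mant$p,
                          n_permutations = mant$n_permutations,
                          seed = mant$seed)
  if (!is.null(wel))
    report$welch <- list(t = wel$t, df = wel$df, p = wel$p)
  write_json_summary(report, file.path(out_dir, "stats_summary.json"))
  invisible(list(het = het_tab, fst = fst, mantel = mant, welch = wel))
}

#' Run the full simulate -> harmonize -> stats pipeline
#'
#' One reproducible command: every stochastic step's seed is derived from
#' the single global seed in the configuration, stage artifacts are written
#' under `out_dir/<stage>/`, the configuration is serialized verbatim, and a
#' combined machine-readable JSON summary is written at the top level.
#'
#' @param config list with elements `seed` (global), `simulate` (arguments
#'   of [sim_config()]; seed defaults to the global seed), `harmonize`
#'   (arguments of [harmonization_config()]), `stats` (list with optional
#'   `n_permutations`); or a path to a YAML file with that structure.
#' @param out_dir output directory.
#' @return list with `sim`, `harmonized`, `stats`, `summary`, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$seed)) stop("config field 'seed' is required")
  seed <- as.integer(config$seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(config, file.path(out_dir, "run_config.yaml"))

  sim_args <- config$simulate
  if (is.null(sim_args)) sim_args <- list()
  if (is.null(sim_args$seed)) sim_args$seed <- seed
  scfg <- do.call(sim_config, sim_args)
  sim <- run_simulate(scfg, file.path(out_dir, "simulate"))
  if (nrow(sim$pairs) == 0)
    stop("usage error: no replicate pairs available for field 'pairs'")

  hcfg <- do.call(harmonization_config,
                  if (is.null(config$harmonize)) list() else config$harmonize)
  harm <- run_harmonize(sim$panels, sim$pairs,
                        file.path(out_dir, "harmonize"), hcfg)

  stats_args <- config$stats
  nperm <- if (is.null(stats_args$n_permutations)) 999L
           else stats_args$n_permutations
  loc_dist <- sim$truth$location_distances
  keep <- rownames(loc_dist) %in% harm$panel$samples$location_code
  st <- run_stats(harm$panel, file.path(out_dir, "stats"),
                  distances = loc_dist[keep, keep],
                  n_permutations = nperm, seed = seed + 1L)

  summary <- list(
    seed = seed,
    harmonize = as.list(harm$summary),
    ledger_conservation =
      unname(harm$summary["n_retained"]) +
      sum(harm$ledger$status$status == "DISCARDED") ==
      unname(harm$summary["n_shared"]),
    stats = list(mean_Ho = mean(st$het$Ho),
                 mantel_r = if (is.null(st$mantel)) NULL else st$mantel$r,
                 mantel_p = if (is.null(st$mantel)) NULL else st$mantel$p))
  write_json_summary(summary, file.path(out_dir, "summary.json"))
  invisible(list(sim = sim, harmonized = harm, stats = st,
                 summary = summary))
}
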