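#' Configuration of a full discovery/validation run
#'
#' Inputs are either file paths (count + metadata TSVs per cohort) or, when
#' paths are `NULL`, a synthetic study generated from `simulation`: both
#' cohorts share one library, the discovery cohort is drawn with seed
#' `simulation$seed + 1` and the validation cohort (its own participants,
#' `n_participants_validation`) with `simulation$seed + 2`.
#'
#' @param simulation A [simulation_config()] (used when no paths are given).
#' @param n_participants_validation Participants in the synthetic validation
#'   cohort.
#' @param counts_discovery,metadata_discovery,counts_validation,metadata_validation
#'   Optional file paths overriding simulation.
#' @param filter A [filter_config()].
#' @param contrasts List of [contrast_spec()]; default [default_contrasts()]
#'   on the simulation's timepoints.
#' @param motif_k Motif length for the family stage.
#' @param top_n Candidates per model group for [select_candidates()].
#' @param out_dir Run directory (created by [run_all()]); excluded from the
#'   reproducibility hash.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(simulation = simulation_config(),
                            n_participants_validation = 17L,
                            counts_discovery = NULL, metadata_discovery = NULL,
                            counts_validation = NULL, metadata_validation = NULL,
                            filter = filter_config(),
                            contrasts = NULL,
                            motif_k = 7L, top_n = 2L,
                            out_dir = NULL) {
  if (is.null(contrasts)) contrasts <- default_contrasts(simulation$timepoints)
  structure(list(simulation = simulation,
                 n_participants_validation = as.integer(n_participants_validation),
                 counts_discovery = counts_discovery,
                 metadata_discovery = metadata_discovery,
                 counts_validation = counts_validation,
                 metadata_validation = metadata_validation,
                 filter = filter, contrasts = contrasts,
                 motif_k = as.integer(motif_k), top_n = top_n,
                 out_dir = out_dir),
            class = "pipeline_config")
}

load_cohorts <- function(config) {
  if (!is.null(config$counts_discovery)) {
    disc <- list(counts = read_counts(config$counts_discovery),
                 metadata = read_metadata(config$metadata_discovery))
    val <- list(counts = read_counts(config$counts_validation),
                metadata = read_metadata(config$metadata_validation))
  } else {
    sim <- config$simulation
    lib <- generate_library(sim)
    disc <- generate_cohort(sim, lib, "discovery", seed = sim$seed + 1L)
    vcfg <- sim
    vcfg$n_participants <- config$n_participants_validation
    val <- generate_cohort(vcfg, lib, "validation", seed = sim$seed + 2L)
  }
  check_samples_match(disc$counts, disc$metadata)
  check_samples_match(val$counts, val$metadata)
  if (length(intersect(disc$metadata$sample_id, val$metadata$sample_id)))
    stop("discovery and validation sample sets overlap")
  list(discovery = disc, validation = val)
}

#' Run the discovery stage
#'
#' Joins sequence families, applies the min-count filter, normalizes to
#' scaled relative-binding values, fits every configured contrast and
#' assembles the descriptive-sequence panels.
#'
#' @param config A [pipeline_config()].
#' @param cohort Optional pre-loaded cohort list (counts, metadata); loaded
#'   or simulated from `config` when `NULL`.
#' @return List: `counts_raw`, `counts_joined`, `counts_filtered`,
#'   `families`, `scaled` (`scaled_matrix`), `results` (per contrast),
#'   `summary`, `panels`, `stage_counts`.
#' @export
run_discovery <- function(config, cohort = NULL) {
  if (is.null(cohort)) cohort <- load_cohorts(config)$discovery
  m <- cohort$counts
  joined <- join_families(m, config$filter)
  filtered <- suppressMessages(filter_min_count(joined$counts, config$filter))
  norm <- normalize_counts(filtered)
  results <- lapply(config$contrasts, function(spec)
    ols_contrast(norm, cohort$metadata, spec))
  summary <- summarize_contrasts(results)
  list(counts_raw = m, counts_joined = joined$counts, counts_filtered = filtered,
       families = joined$families, scaled = norm, metadata = cohort$metadata,
       results = results, summary = summary$table, panels = summary$panels,
       stage_counts = c(raw = nrow(m), joined = nrow(joined$counts),
                        filtered = nrow(filtered),
                        descriptive = length(unique(unlist(summary$panels)))))
}

#' Run the validation stage on frozen panels
#'
#' The validation cohort is processed independently (its own family joining,
#' filtering and per-sequence means), then each condition's frozen
#' discovery panel is tested with [validate_panel()].  Conditions with an
#' empty panel are skipped with a notice.
#'
#' @param config A [pipeline_config()].
#' @param panels Named list (condition -> sequences) frozen from discovery.
#' @param cohort Optional pre-loaded validation cohort.
#' @return List: `validations` (per condition [validate_panel()] objects),
#'   `counts_filtered`, `scaled`, `skipped` (conditions with empty panels).
#' @export
run_validation <- function(config, panels, cohort = NULL) {
  if (is.null(cohort)) cohort <- load_cohorts(config)$validation
  joined <- join_families(cohort$counts, config$filter)
  filtered <- suppressMessages(filter_min_count(joined$counts, config$filter))
  norm <- normalize_counts(filtered)
  conditions <- intersect(c("sampling_time", "bmi_group", "parity"), names(panels))
  skipped <- setdiff(c("sampling_time", "bmi_group", "parity"), conditions)
  validations <- lapply(setNames(conditions, conditions), function(cond)
    validate_panel(norm, cohort$metadata, panels[[cond]], grouping = cond,
                   timepoints = config$simulation$timepoints))
  if (length(skipped))
    message("validation skipped for condition(s) without descriptive sequences: ",
            paste(skipped, collapse = ", "))
  list(validations = validations, counts_filtered = filtered, scaled = norm,
       metadata = cohort$metadata, skipped = skipped)
}

config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$out_dir <- NULL
  cfg$simulation <- unclass(cfg$simulation)
  cfg$filter <- unclass(cfg$filter)
  cfg$contrasts <- lapply(cfg$contrasts, unclass)
  json <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA, force = TRUE)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(json, tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full discovery-to-validation workflow
#'
#' Executes discovery, freezes the descriptive panels, runs validation,
#' builds motif families over the pooled panels and selects candidate
#' aptamers; writes every stage output plus a reproducibility manifest to
#' `config$out_dir` (when set).  Re-running with the same configuration
#' reproduces all outputs bit-identically: the manifest records the config
#' hash, seed, package version and the row counts at every stage, and
#' contains no timestamps.
#'
#' @param config A [pipeline_config()].
#' @return Report list (also written as `report.json`): stage counts,
#'   per-contrast summary, panel sizes, validation Wilcoxon p values,
#'   motif-family table and candidate selection.
#' @export
run_all <- function(config) {
  cohorts <- load_cohorts(config)
  disc <- run_discovery(config, cohorts$discovery)
  val <- run_validation(config, disc$panels, cohorts$validation)

  motif_tab <- NULL; families <- NULL; candidates <- NULL
  panel_all <- sort(unique(unlist(disc$panels)))
  if (length(panel_all) >= 1) {
    motif_tab <- motif_enrichment(panel_all, rownames(disc$counts_filtered),
                                  k = config$motif_k)
    enriched <- motif_tab$motif[motif_tab$enriched]
    total_reads <- rowSums(disc$counts_filtered)
    vtot <- rowSums(val$counts_filtered)
    shared <- intersect(names(total_reads), names(vtot))
    total_reads[shared] <- total_reads[shared] + vtot[shared]
    families <- build_families(enriched, disc$panels, total_reads)
    candidates <- select_candidates(families, total_reads, top_n = config$top_n)
  }

  wilcoxon <- do.call(rbind, lapply(names(val$validations), function(cond) {
    w <- val$validations[[cond]]$wilcoxon
    cbind(condition = cond, w)
  }))
  report <- list(
    config_hash = config_hash(config),
    seed = config$simulation$seed,
    package_version = as.character(utils::packageVersion("aptaprofile")),
    stage_counts = as.list(disc$stage_counts),
    contrast_summary = disc$summary,
    panel_sizes = lapply(disc$panels, length),
    validation_wilcoxon = wilcoxon,
    validation_coverage = lapply(val$validations, `[[`, "panel_coverage"),
    n_motif_enriched = if (is.null(motif_tab)) 0L else sum(motif_tab$enriched),
    n_families = if (is.null(families)) 0L else nrow(families),
    n_candidates = if (is.null(candidates)) 0L else nrow(candidates)
  )

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    out <- function(f) file.path(config$out_dir, f)
    write_counts(disc$counts_filtered, out("discovery_filtered_counts.tsv"))
    write_metadata(disc$metadata, out("discovery_metadata.tsv"))
    write_counts(val$counts_filtered, out("validation_filtered_counts.tsv"))
    write_metadata(val$metadata, out("validation_metadata.tsv"))
    for (i in seq_along(disc$results))
      write.table(disc$results[[i]],
                  out(sprintf("ols_%s.tsv", gsub("[:/]", "_", disc$results[[i]]$contrast[1]))),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(disc$summary, out("contrast_summary.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    for (cond in names(disc$panels))
      write_panel_fasta(disc$panels[[cond]], out(sprintf("panel_%s.fasta", cond)))
    if (!is.null(wilcoxon))
      write.table(wilcoxon, out("validation_wilcoxon.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    if (!is.null(motif_tab))
      write.table(motif_tab, out("motifs.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
    if (!is.null(families))
      write.table(as.data.frame(families), out("families.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    if (!is.null(candidates) && nrow(candidates))
      write_panel_fasta(candidates$candidate, out("candidates.fasta"))
    manifest <- list(config_hash = report$config_hash, seed = report$seed,
                     package_version = report$package_version,
                     stage_counts = report$stage_counts)
    jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, dataframe = "rows")
  }
  invisible(c(report, list(discovery = disc, validation = val,
                           motifs = motif_tab, families = families,
                           candidates = candidates)))
}
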