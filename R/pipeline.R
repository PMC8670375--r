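#' Run the full compartment-resolved LFQ pipeline
#'
#' Executes qualification, presence calling, differential abundance,
#' aggregation and (optionally) the secretion statistics in order on an
#' already-validated quantification table, collects all stage outputs in
#' one bundle, and records a run manifest (package version, configuration
#' hash, seed and per-stage row counts). With an output directory every
#' stage table is additionally written as a TSV whose header comment
#' carries the version and configuration hash. Identical inputs,
#' configuration and seed yield identical bundles.
#'
#' @param quant A validated quantification tibble (see
#'   [read_quant_table()] / [validate_quant_table()]).
#' @param maps An [annotation_maps()] object.
#' @param min_unique_peptides,min_replicates Qualification thresholds.
#' @param s0,n_randomizations,fdr,method,var_equal Differential-test
#'   settings, see [diff_abundance()].
#' @param seed Integer seed propagated to every stochastic stage.
#' @param tally_by,tally_level Grouping for [tally_regulation()].
#' @param secretion Compute the Sec-proportion statistics (requires a
#'   provided signal-peptide map).
#' @param deleted Optional character vector of gene-deleted proteins,
#'   forwarded to [treemap_export()].
#' @param out_dir Optional directory for the stage TSVs.
#' @return A list of class `secretomics_run` with elements qualified,
#'   presence, diff, classed, tally, core, altered, secretion,
#'   mislocalized and manifest.
#' @export
#' @examples
#' sim <- simulate_quant_experiment(sim_config(n_proteins = 120, seed = 3))
#' run <- run_pipeline(sim$quant, sim$annotations, seed = 3)
#' run$manifest$row_counts
run_pipeline <- function(quant, maps,
                         min_unique_peptides = 2, min_replicates = 2,
                         s0 = 0.1, n_randomizations = 250, fdr = 0.05,
                         method = c("permutation", "bh"),
                         var_equal = TRUE,
                         seed = NULL,
                         tally_by = "category", tally_level = 2,
                         secretion = TRUE,
                         deleted = character(),
                         out_dir = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(maps, "annotation_maps"))
  config <- list(min_unique_peptides = min_unique_peptides,
                 min_replicates = min_replicates, s0 = s0,
                 n_randomizations = n_randomizations, fdr = fdr,
                 method = method, var_equal = var_equal, seed = seed,
                 tally_by = tally_by, tally_level = tally_level,
                 secretion = secretion)

  # validate everything the enabled stages need before any computation
  provided <- attr(maps, "provided")
  if (secretion && !isTRUE(provided[["sec_sp"]])) {
    stop_secretomics(
      "Secretion stage enabled but no signal-peptide map was provided.",
      class = "secretomics_validation_error")
  }

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Stage '%s' failed: %s", name, conditionMessage(e)),
            class = "secretomics_stage_error",
            stage = name, parent = e)
    })
  }

  qualified <- stage("qualify",
    qualify_proteins(quant, maps,
                     min_unique_peptides = min_unique_peptides,
                     min_replicates = min_replicates))
  presence <- stage("presence", call_presence(qualified))
  diff <- stage("diffstat",
    diff_abundance(quant, presence, s0 = s0,
                   n_randomizations = n_randomizations, fdr = fdr,
                   seed = seed, method = method, var_equal = var_equal))
  classed <- stage("classify", classify_regulation(diff, presence))
  tally <- stage("aggregate",
    tally_regulation(classed, maps, by = tally_by, level = tally_level))
  core <- stage("aggregate", core_proteome(qualified))
  altered <- stage("aggregate", total_altered(classed))
  sec <- NULL
  misloc <- NULL
  if (secretion) {
    sec <- stage("secretion", sec_proportion(quant, qualified, maps))
    misloc <- stage("secretion", mislocalization_check(qualified, maps))
  }

  manifest <- list(
    package_version = as.character(packageVersion("secretomics")),
    config = config,
    config_hash = rlang::hash(config),
    seed = seed,
    row_counts = list(quant = nrow(quant),
                      qualified = nrow(qualified),
                      presence = nrow(presence),
                      diff = nrow(diff),
                      classed = nrow(classed),
                      tally = nrow(tally)))

  bundle <- structure(
    list(qualified = qualified, presence = presence, diff = diff,
         classed = classed, tally = tally, core = core, altered = altered,
         secretion = sec, mislocalized = misloc, manifest = manifest),
    class = "secretomics_run")

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_stage_tsv(qualified, file.path(out_dir, "qualified.tsv"), config)
    write_stage_tsv(presence, file.path(out_dir, "presence.tsv"), config)
    write_stage_tsv(as_tibble(diff), file.path(out_dir, "diff.tsv"), config)
    write_stage_tsv(as_tibble(classed), file.path(out_dir, "classed.tsv"),
                    config)
    write_stage_tsv(tally, file.path(out_dir, "tally.tsv"), config)
    write_stage_tsv(core$regions, file.path(out_dir, "venn_regions.tsv"),
                    config)
    write_stage_tsv(altered, file.path(out_dir, "total_altered.tsv"), config)
    if (!is.null(sec)) {
      write_stage_tsv(sec$summary, file.path(out_dir, "secretion.tsv"),
                      config)
      write_stage_tsv(misloc, file.path(out_dir, "mislocalized.tsv"),
                      config)
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  bundle
}

#' @export
print.secretomics_run <- function(x, ...) {
  cat("<secretomics_run>\n")
  cat("  proteins tested:", nrow(x$diff), "\n")
  cat("  significant:", sum(x$diff$significant, na.rm = TRUE), "\n")
  cat("  core proteome:", x$core$core, "\n")
  alt <- paste(sprintf("%s=%d", x$altered$strain, x$altered$n_altered),
               collapse = ", ")
  cat("  altered proteins:", alt, "\n")
  invisible(x)
}
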