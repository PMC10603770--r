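#' Pipeline entry points
#'
#' Thin orchestration over the package's building blocks, mirroring the
#' stages a mapping study runs from the shell: `run_simulate()` writes a
#' VCF plus ground-truth tables, `run_filter()` applies the filter
#' cascade to a VCF, `run_map()` infers phases and estimates the map,
#' `run_evaluate()` compares an estimated map against simulated truth,
#' and `run_pipeline()` chains all of them. Every run writes a
#' `provenance.json` with the configuration, seed and package version.
#' A command-line wrapper over these functions is installed at
#' `system.file("cli", "fsmapr.R", package = "fsmapr")`.
#'
#' @name pipeline
NULL

write_provenance <- function(outdir, stage, params) {
  jsonlite::write_json(
    list(stage = stage, params = params,
         package = "fsmapr",
         version = as.character(packageVersion("fsmapr")),
         time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    file.path(outdir, paste0("provenance_", stage, ".json")),
    auto_unbox = TRUE, pretty = TRUE, digits = NA, force = TRUE)
}

#' Simulate a dataset and write its artifacts
#'
#' Writes `simulated.vcf`, `true_map.tsv`, `true_genotypes.tsv`,
#' `gamete_origins.tsv` and `sim_config.json` under `outdir`.
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @param outdir output directory (created if needed).
#' @param observe passed to [simulate_f1()].
#' @return the [simulate_f1()] result, invisibly.
#' @export
run_simulate <- function(config = sim_config(), seed = 1L, outdir,
                         observe = "depths") {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_f1(config, seed, observe)
  write_vcf(sim$dataset, file.path(outdir, "simulated.vcf"))
  tm <- data.frame(id = sim$truth$markers$id,
                   chrom = sim$truth$markers$chrom,
                   pos_bp = sim$truth$markers$pos_bp,
                   type = sim$truth$markers$type,
                   cm = sim$truth$markers$cm)
  write.table(tm, file.path(outdir, "true_map.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(sim$truth$geno, file.path(outdir, "true_genotypes.tsv"),
              sep = "\t", quote = FALSE, col.names = NA)
  og <- data.frame(progeny = rep(colnames(sim$truth$origin_p1),
                                 each = nrow(sim$truth$origin_p1)),
                   marker = rep(sim$truth$markers$id,
                                ncol(sim$truth$origin_p1)),
                   p1_homolog = as.vector(sim$truth$origin_p1),
                   p2_homolog = as.vector(sim$truth$origin_p2))
  write.table(og, file.path(outdir, "gamete_origins.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  cfg <- unclass(config)
  cfg$seed <- seed
  cfg$observe <- observe
  jsonlite::write_json(cfg, file.path(outdir, "sim_config.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  write_provenance(outdir, "simulate", list(seed = seed, observe = observe))
  message("simulate: wrote ", nrow(sim$dataset$markers), " markers x ",
          ncol(sim$dataset$geno), " progeny to ", outdir)
  invisible(sim)
}

#' Filter a VCF and write the reduced dataset
#'
#' @param vcf input VCF path.
#' @param parent1_id,parent2_id parent sample names.
#' @param outdir output directory.
#' @param sanitize_ad zero out AD/DP of missing calls first.
#' @param ... thresholds passed to [apply_filters()].
#' @return list with `dataset` and `reports`, invisibly.
#' @export
run_filter <- function(vcf, parent1_id, parent2_id, outdir,
                       sanitize_ad = TRUE, ...) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  dataset <- read_vcf(vcf, parent1_id, parent2_id)
  if (sanitize_ad) dataset <- sanitize_allele_depths(dataset)
  res <- apply_filters(dataset, ...)
  write_vcf(res$dataset, file.path(outdir, "filtered.vcf"))
  write_filter_report(res$reports, file.path(outdir, "filter_report.json"))
  write_provenance(outdir, "filter",
                   list(vcf = vcf, parents = c(parent1_id, parent2_id),
                        sanitize_ad = sanitize_ad, ...))
  invisible(res)
}

#' Build a linkage map from a filtered dataset or VCF
#'
#' Infers phases along the genomic order, estimates the map, decodes
#' progeny haplotypes, and writes `map.tsv`, `haplotypes.tsv` and (for
#' small marker sets) `rf_matrix.tsv`.
#'
#' @param x a `marker_dataset` or a VCF path.
#' @param parent1_id,parent2_id parent sample names (VCF input only).
#' @param outdir output directory.
#' @param mode,global_error error model (see [create_priors()]).
#' @param mapfunc `"haldane"` or `"kosambi"`.
#' @param rf_matrix_max write the pairwise rf matrix when the map has at
#'   most this many markers (quadratic cost).
#' @return the `linkage_map`, invisibly.
#' @export
run_map <- function(x, parent1_id = NULL, parent2_id = NULL, outdir,
                    mode = "global_error", global_error = 0.05,
                    mapfunc = "haldane", rf_matrix_max = 60L) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  dataset <- if (inherits(x, "marker_dataset")) x
             else read_vcf(x, parent1_id, parent2_id)
  keep <- informative_markers(dataset)
  dataset <- subset_markers(dataset, keep)
  message("map: ", length(keep), " informative markers, mode=", mode,
          if (mode != "genotype_probs") paste0(", error=", global_error))
  phases <- infer_phases(dataset, mode, global_error)
  map <- estimate_map(dataset, phases, mode, global_error, mapfunc,
                      rf_init = attr(phases, "rf"))
  export_map_tsv(map, file.path(outdir, "map.tsv"))
  haps <- decode_haplotypes(map)
  export_haplotypes_tsv(haps, file.path(outdir, "haplotypes.tsv"))
  if (nrow(map$markers) <= rf_matrix_max) {
    rfm <- rf_matrix(dataset, mode, global_error)
    ut <- rfm$rf; ut[lower.tri(ut, diag = TRUE)] <- NA
    write.table(round(ut, 5), file.path(outdir, "rf_matrix.tsv"),
                sep = "\t", quote = FALSE, col.names = NA)
  }
  write_provenance(outdir, "map",
                   list(mode = mode, global_error = global_error,
                        mapfunc = mapfunc))
  message("map: total length ", sprintf("%.2f", map_length(map)), " cM (",
          mapfunc, "), loglik ", sprintf("%.2f", map$loglik))
  invisible(map)
}

#' Evaluate an estimated map against simulated truth
#'
#' Writes `evaluation.json` (map summary, Euclidean distance,
#' breakpoint accounting) and `breakpoints.tsv`.
#'
#' @param map a `linkage_map`.
#' @param truth a `sim_truth`.
#' @param outdir output directory.
#' @return the evaluation list, invisibly.
#' @export
run_evaluate <- function(map, truth, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ms <- map_summary(map)
  dist <- euclidean_map_distance(map, truth)
  haps <- decode_haplotypes(map)
  bp <- breakpoint_error_summary(haps, truth)
  out <- list(n_markers = ms$n_markers,
              type_counts = as.list(ms$type_counts),
              total_cm = ms$total_cm, max_gap_cm = ms$max_gap_cm,
              n_gaps_over = ms$n_gaps_over,
              outlier_markers = ms$outlier_markers,
              euclidean_distance = dist,
              overestimated_breakpoints = bp$overestimated,
              underestimated_breakpoints = bp$underestimated,
              wrong_breakpoints = bp$wrong)
  jsonlite::write_json(out, file.path(outdir, "evaluation.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  write.table(bp$per_progeny, file.path(outdir, "breakpoints.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_provenance(outdir, "evaluate", list())
  message("evaluate: ", sprintf("%.2f cM, D=%.3f, wrong breakpoints=%d",
                                ms$total_cm, dist, bp$wrong))
  invisible(out)
}

#' Run the full simulate-filter-map-evaluate pipeline
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @param outdir output directory.
#' @param mode,global_error,mapfunc passed to [run_map()].
#' @param ... filter thresholds passed to [apply_filters()].
#' @return list with `sim`, `filtered`, `map`, `evaluation`, invisibly.
#' @export
run_pipeline <- function(config = sim_config(), seed = 1L, outdir,
                         mode = "global_error", global_error = 0.05,
                         mapfunc = "haldane", ...) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sim <- run_simulate(config, seed, outdir)
  filtered <- run_filter(file.path(outdir, "simulated.vcf"), "P1", "P2",
                         outdir, ...)
  map <- run_map(filtered$dataset, outdir = outdir, mode = mode,
                 global_error = global_error, mapfunc = mapfunc)
  evaluation <- run_evaluate(map, sim$truth, outdir)
  invisible(list(sim = sim, filtered = filtered, map = map,
                 evaluation = evaluation))
}
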