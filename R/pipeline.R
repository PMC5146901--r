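#' Build a pipeline run configuration
#'
#' Collects the thresholds, gene panels and simulation settings of one
#' end-to-end analysis run. Defaults reproduce the study design: per tissue
#' 26 target genes (15 clock + 11 myogenic) with published cosinor
#' parameters as generating truth, 6 reference candidates, 9 Zeitgeber times
#' (ZT0..24 every 3 h), 6 replicates.
#'
#' @param tissue `"fast"` or `"slow"`.
#' @param seed Integer root seed.
#' @param noise_sd Log2 noise scale of the simulated targets.
#' @param rhythm_threshold Cutoff on P = SE(A)/A, in (0, 1].
#' @param min_abs_r Correlation magnitude gate.
#' @param alpha Duncan/ANOVA significance level.
#' @param calibrator ddCt calibrator rule.
#' @param fit_on Cosinor fitting mode (see [rhythm_table()]).
#' @param genes,references Optional custom [gene_spec()] lists overriding the
#'   default panels; target panels must be disjoint from reference candidates.
#' @return A `run_config` object (named list).
#' @export
run_config <- function(tissue = c("fast", "slow"), seed = 1L, noise_sd = 0.1,
                       rhythm_threshold = 0.3, min_abs_r = 0.5, alpha = 0.05,
                       calibrator = "global_mean",
                       fit_on = "replicates",
                       genes = NULL, references = NULL) {
  tissue <- match.arg(tissue)
  stopifnot(rhythm_threshold > 0, rhythm_threshold <= 1,
            min_abs_r > 0, alpha > 0, alpha < 1)
  if (is.null(genes)) genes <- default_gene_panel(tissue, noise_sd = noise_sd)
  if (is.null(references)) references <- reference_panel()
  tn <- vapply(genes, `[[`, character(1), "name")
  rn <- vapply(references, `[[`, character(1), "name")
  if (length(intersect(tn, rn))) {
    stop("target and reference panels overlap: ",
         paste(intersect(tn, rn), collapse = ", "))
  }
  structure(list(tissue = tissue, seed = as.integer(seed),
                 noise_sd = noise_sd, rhythm_threshold = rhythm_threshold,
                 min_abs_r = min_abs_r, alpha = alpha,
                 calibrator = calibrator, fit_on = fit_on,
                 genes = genes, references = references),
            class = "run_config")
}

#' Read a run configuration from JSON
#'
#' The JSON schema mirrors [run_config()]: scalar fields by the same names,
#' plus optional `genes` / `references` arrays of objects with fields
#' `name`, `mesor`, `amplitude`, `acrophase`, `noise_sd`, `role`.
#'
#' @param path Path to a JSON file.
#' @return A `run_config` object.
#' @export
read_run_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  parse_panel <- function(lst) {
    if (is.null(lst)) return(NULL)
    lapply(lst, function(g) do.call(gene_spec, g))
  }
  args <- j[intersect(names(j), c("tissue", "seed", "noise_sd",
                                  "rhythm_threshold", "min_abs_r", "alpha",
                                  "calibrator", "fit_on"))]
  args <- lapply(args, function(v) if (is.list(v)) unlist(v) else v)
  args$genes <- parse_panel(j$genes)
  args$references <- parse_panel(j$references)
  do.call(run_config, args)
}

#' Run the full daily-rhythmicity pipeline
#'
#' Simulates a raw Ct dataset under the configured design, selects the
#' reference gene(s) by geNorm, quantifies relative expression by 2^-ddCt,
#' fits per-gene cosinors and flags rhythmicity, computes per-timepoint
#' ANOVA with Duncan letters, and screens rhythm-gated Pearson correlations
#' between the clock-gene and myogenic-gene panels. Identical configurations
#' (including seed) give identical results.
#'
#' @param config A [run_config()].
#' @param out_dir Optional directory; when given, writes `rhythm_<tissue>.csv`,
#'   `group_stats_<tissue>.csv`, `correlations_<tissue>.csv`,
#'   `expression_<tissue>.csv` and a `manifest_<tissue>.json` run manifest.
#' @return List with elements `ct`, `genorm`, `reference`, `expression`,
#'   `rhythm`, `group_stats`, `correlations`, `config`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  design <- study_design(seed = config$seed)
  all_specs <- c(config$genes, config$references)
  ct <- generate_ct_dataset(all_specs, design, prefix = config$tissue)

  ref_names <- vapply(config$references, `[[`, character(1), "name")
  ref_ct <- ct[ct$gene %in% ref_names, c("sample_id", "gene", "ct")]
  ref_q <- data.frame(sample_id = ref_ct$sample_id, gene = ref_ct$gene,
                      value = 2^(-ref_ct$ct), stringsAsFactors = FALSE)
  gn <- genorm_m(ref_q)
  reference <- select_reference(gn, mode = "single")

  targets <- vapply(config$genes, `[[`, character(1), "name")
  expr <- delta_delta_ct(ct, targets, reference,
                         calibrator = config$calibrator)
  rhythm <- rhythm_table(expr, genes = targets, fit_on = config$fit_on,
                         threshold = config$rhythm_threshold)
  gstats <- group_stats_table(expr, genes = targets, alpha = config$alpha)
  clock_set <- intersect(targets, clock_genes())
  myo_set <- intersect(targets, myogenic_genes())
  corr <- correlation_table(expr, rhythm,
                            gene_set_a = if (length(clock_set)) clock_set else targets,
                            gene_set_b = targets,
                            min_abs_r = config$min_abs_r)
  res <- list(ct = ct, genorm = gn, reference = reference,
              expression = expr, rhythm = rhythm, group_stats = gstats,
              correlations = corr, config = config)
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

write_pipeline_outputs <- function(res, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  tis <- res$config$tissue
  w <- function(df, name) {
    utils::write.csv(df, file.path(out_dir, sprintf("%s_%s.csv", name, tis)),
                     row.names = FALSE)
  }
  w(res$expression, "expression")
  w(res$rhythm, "rhythm")
  w(res$group_stats, "group_stats")
  w(res$correlations[res$correlations$gate_passed, , drop = FALSE],
    "correlations")
  manifest <- list(
    tissue = tis, seed = res$config$seed,
    thresholds = list(rhythm = res$config$rhythm_threshold,
                      min_abs_r = res$config$min_abs_r,
                      alpha = res$config$alpha),
    calibrator = res$config$calibrator,
    reference_gene = res$reference,
    genorm_ranking = res$genorm$ranking,
    n_genes = length(res$config$genes),
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("rhythmoscope")))
  jsonlite::write_json(manifest,
                       file.path(out_dir, sprintf("manifest_%s.json", tis)),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(res)
}

#' Read or write long-format expression / Ct tables
#'
#' Headered CSV with columns `sample_id`, `gene`, `zt`, `replicate` and a
#' value column (`value` for expression, `ct` for cycle thresholds). Gene
#' names are normalised on ingest.
#'
#' @param path CSV file path.
#' @param table Data frame to write.
#' @return `read_expression_table()` returns a data frame.
#' @export
read_expression_table <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "gene", "zt", "replicate")
  missing <- setdiff(need, names(d))
  if (length(missing)) stop("missing column(s): ",
                            paste(missing, collapse = ", "))
  d$gene <- normalize_gene_names(d$gene)
  d
}

#' @rdname read_expression_table
#' @export
write_expression_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}
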