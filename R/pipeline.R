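#' Run the full cross-species overlap pipeline
#'
#' Executes the stage chain: TPM normalisation (when counts are supplied)
#' -> cumulative-TPM abundance filter -> per-gene differential test ->
#' enriched-set selection -> single-copy orthogroup restriction ->
#' projection of the enriched and target sets -> Monte Carlo overlap test;
#' optionally the alien-index contamination screen. Inputs may be in-memory
#' objects or file paths in the package's standard formats.
#'
#' Threshold defaults are the conventional ones for this analysis: fold
#' change at least 5, raw p at most 0.05, cumulative TPM at least 0.1,
#' 10,000 Monte Carlo iterations, alien-index cutoff 40.
#'
#' @param study an [expression_study()], or path to a counts/TPM TSV (then
#'   `sample_groups` is required).
#' @param orthogroups an `orthogroup_table` or path to an
#'   OrthoFinder-dialect TSV.
#' @param target a [gene_set()] of species-B genes or path to a one-ID-per-
#'   line file.
#' @param blast optional labelled BLAST hit data.frame, or path to an
#'   outfmt-6 file (then `subject_groups` is required).
#' @param subject_groups subject-to-group map for `blast` (data.frame,
#'   named vector, or two-column TSV path).
#' @param sample_groups sample-to-group labels when `study` is a path.
#' @param value_kind `"counts"` or `"tpm"` when `study` is a path.
#' @param min_fold,max_p,min_cumulative_tpm enrichment thresholds.
#' @param ai_cutoff alien-index flagging cutoff.
#' @param B Monte Carlo iterations.
#' @param seed seed for the Monte Carlo draw (recorded in the report).
#' @param out_dir optional directory; when given, per-stage TSVs, the
#'   overlap JSON report and a run log are written there.
#' @param quiet suppress the per-stage funnel messages.
#' @return A list of class `"pipeline_report"`: `thresholds`, `funnel`
#'   (named stage cardinalities), `de_table`, `enriched` ([gene_set()]),
#'   `single_copy` map, `overlap` (an `"overlap_test"` with gene-level
#'   fields), and `contamination` (summary list or `NULL`).
#' @export
run_pipeline <- function(study, orthogroups, target,
                         blast = NULL, subject_groups = NULL,
                         sample_groups = NULL,
                         value_kind = "counts",
                         min_fold = 5, max_p = 0.05,
                         min_cumulative_tpm = 0.1,
                         ai_cutoff = 40,
                         B = 10000, seed = NULL,
                         out_dir = NULL, quiet = FALSE) {
  say <- function(stage, fmt, ...) {
    if (!quiet) message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
  }
  if (is.character(study)) {
    if (is.null(sample_groups)) {
      stop("sample_groups required when study is a file path", call. = FALSE)
    }
    study <- read_expression_tsv(study, sample_groups = sample_groups,
                                 value_kind = value_kind)
  }
  if (is.character(orthogroups)) orthogroups <- read_orthogroups(orthogroups)
  if (is.character(target)) target <- read_gene_set(target, species = "B")
  stopifnot(inherits(study, "expression_study"),
            inherits(orthogroups, "orthogroup_table"),
            inherits(target, "gene_set"))

  n_input <- nrow(study$values)
  if (study$value_kind == "counts") {
    study <- compute_tpm(study)
    say("tpm", "normalised %d genes x %d samples to TPM",
        nrow(study$values), ncol(study$values))
  }
  de <- differential_test(study, min_cumulative_tpm = min_cumulative_tpm)
  n_abund <- sum(de$passed_abundance)
  say("abundance", "%d of %d genes at cumulative TPM >= %g",
      n_abund, n_input, min_cumulative_tpm)

  enriched <- select_enriched(de, min_fold = min_fold, max_p = max_p)
  say("enriched", "%d genes at fold >= %g and p <= %g",
      length(enriched), min_fold, max_p)

  scm <- single_copy_map(orthogroups)
  say("single-copy", "%d of %d orthogroups single-copy",
      length(scm), length(orthogroups$orthogroup_ids))

  ov <- overlap_analysis(enriched, target, scm, B = B, seed = seed)
  say("project", "enriched %d -> %d orthogroups; target %d -> %d",
      length(enriched), ov$n, length(target), ov$K)
  say("overlap", "k_obs = %d of universe %d; corrected p = %.3g",
      ov$k_obs, ov$N, ov$p_mc_corrected)

  contamination <- NULL
  if (!is.null(blast)) {
    if (is.character(blast)) {
      blast <- read_blast_outfmt6(blast)
      if (is.character(subject_groups)) {
        subject_groups <- read.delim(subject_groups, header = FALSE,
                                     stringsAsFactors = FALSE)
      }
      if (is.null(subject_groups)) {
        stop("subject_groups required with a raw BLAST report",
             call. = FALSE)
      }
      blast <- label_blast_hits(blast, subject_groups)
    }
    records <- alien_index_records(
      best_hits(blast, queries = study$gene_ids), cutoff = ai_cutoff)
    contamination <- contamination_summary(records, cutoff = ai_cutoff)
    contamination$records <- records
    say("contamination", "%.2f%% outgroup-best, %.2f%% AI > %g",
        100 * contamination$frac_outgroup_best,
        100 * contamination$frac_flagged, ai_cutoff)
  }

  report <- structure(list(
    thresholds = list(min_fold = min_fold, max_p = max_p,
                      min_cumulative_tpm = min_cumulative_tpm,
                      ai_cutoff = ai_cutoff, B = B, seed = seed),
    funnel = c(input_genes = n_input, abundance_passed = n_abund,
               enriched = length(enriched),
               single_copy_universe = length(scm),
               projected_enriched = ov$n, projected_target = ov$K,
               overlap = ov$k_obs),
    de_table = de, enriched = enriched, single_copy = scm,
    overlap = ov, contamination = contamination
  ), class = "pipeline_report")

  if (!is.null(out_dir)) write_pipeline_outputs(report, out_dir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("pipeline_report\n  funnel:\n")
  for (s in names(x$funnel)) {
    cat(sprintf("    %-22s %d\n", s, x$funnel[[s]]))
  }
  cat(sprintf("  overlap: k = %d, corrected p = %.3g (exact %.3g)\n",
              x$overlap$k_obs, x$overlap$p_mc_corrected, x$overlap$p_exact))
  if (!is.null(x$contamination)) {
    cat(sprintf("  contamination: %.2f%% outgroup-best, %.2f%% flagged\n",
                100 * x$contamination$frac_outgroup_best,
                100 * x$contamination$frac_flagged))
  }
  invisible(x)
}

write_pipeline_outputs <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  write.table(report$de_table, p("de_table.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_gene_set(report$enriched, p("enriched_genes.txt"))
  jsonlite::write_json(
    list(thresholds = report$thresholds,
         enriched_provenance = report$enriched$provenance,
         n_enriched = length(report$enriched)),
    p("enriched_genes.json"), auto_unbox = TRUE, digits = NA)
  write_overlap_report(report$overlap, p("overlap_report.json"))
  log <- c(
    sprintf("thresholds: fold>=%g p<=%g cumTPM>=%g B=%d seed=%s",
            report$thresholds$min_fold, report$thresholds$max_p,
            report$thresholds$min_cumulative_tpm, report$thresholds$B,
            report$thresholds$seed %||% "NULL"),
    sprintf("funnel: %s",
            paste(sprintf("%s=%d", names(report$funnel), report$funnel),
                  collapse = " "))
  )
  if (!is.null(report$contamination)) {
    write.table(report$contamination$records, p("alien_index.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    log <- c(log, sprintf(
      "contamination: outgroup_best=%.4f flagged=%.4f cutoff=%g",
      report$contamination$frac_outgroup_best,
      report$contamination$frac_flagged, report$contamination$cutoff))
  }
  writeLines(log, p("run_log.txt"))
  invisible(out_dir)
}

#' Load a pipeline configuration from YAML
#'
#' Reads a YAML file whose keys mirror [run_pipeline()] arguments (input
#' paths under `inputs:`, thresholds under `thresholds:`) and returns an
#' argument list suitable for `do.call(run_pipeline, ...)`. Used by the
#' command-line wrapper in `inst/scripts/overlap-pipeline.R`.
#'
#' @param path YAML file path.
#' @return Named list of [run_pipeline()] arguments.
#' @export
pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the `yaml` package is needed to read YAML configs", call. = FALSE)
  }
  cfg <- yaml::read_yaml(path)
  inputs <- cfg$inputs %||% list()
  thresholds <- cfg$thresholds %||% list()
  groups <- inputs$sample_groups
  if (!is.null(groups)) groups <- unlist(groups)
  args <- list(
    study = inputs$counts %||% inputs$tpm,
    value_kind = if (!is.null(inputs$tpm)) "tpm" else "counts",
    sample_groups = groups,
    orthogroups = inputs$orthogroups,
    target = inputs$target,
    blast = inputs$blast,
    subject_groups = inputs$subject_groups
  )
  for (k in c("min_fold", "max_p", "min_cumulative_tpm", "ai_cutoff", "B",
              "seed")) {
    if (!is.null(thresholds[[k]])) args[[k]] <- thresholds[[k]]
  }
  if (!is.null(cfg$out_dir)) args$out_dir <- cfg$out_dir
  args[!vapply(args, is.null, logical(1))]
}
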