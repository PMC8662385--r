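#' Configuration for the two-species synthetic generator
#'
#' Describes a synthetic two-species study: orthogroup composition,
#' negative-binomial replicate counts for species A, a planted
#' tissue-enriched gene set, a planted target ("dependent") set in species
#' B realising an exact overlap with the enriched set's orthologs, and a
#' planted contaminant fraction for the BLAST screen.
#'
#' @param n_single_copy single-copy orthogroups (one gene per species).
#' @param n_multi_copy multi-copy orthogroups; each carries 2--4 genes
#'   (uniform) in one randomly chosen species and 1 in the other, so they
#'   are excluded by the single-copy restriction.
#' @param n_species_specific_A,n_species_specific_B genes placed in
#'   single-species orthogroups (empty cell for the other species).
#' @param replicates replicates per group (tissue and body); must be >= 1,
#'   >= 2 for the differential test.
#' @param nb_mean_range range of baseline negative-binomial mean counts,
#'   sampled log-uniformly per gene.
#' @param nb_dispersion NB dispersion alpha (variance = mu + alpha mu^2).
#' @param length_range gene effective-length range in bases, sampled
#'   log-uniformly, so TPM is not proportional to counts.
#' @param planted_enriched_size genes whose group-A (tissue) mean is
#'   multiplied by `planted_fold`.
#' @param planted_fold fold multiplier (>= 1; 1 gives a global null).
#' @param planted_mean_range baseline-mean range for planted enriched
#'   genes (log-uniform). Kept moderate by default (50--200) so the
#'   planted effect is large relative to counting noise while the extra
#'   reads shift the TPM composition only modestly (the realised TPM fold
#'   change is always below `planted_fold` because enriched reads inflate
#'   the tissue library).
#' @param planted_enriched_nonortho how many of the planted enriched genes
#'   are drawn from species-specific A genes (outside the single-copy
#'   universe); the remainder are single-copy genes.
#' @param planted_target_size species-B target genes drawn from single-copy
#'   orthogroups.
#' @param planted_overlap exact number of orthogroups shared between the
#'   enriched set's single-copy projection and the target set.
#' @param planted_target_nonortho extra target genes drawn from
#'   species-specific B genes (they do not project into the universe).
#' @param contaminant_fraction fraction of species-A transcripts planted as
#'   contaminants in the BLAST screen (strong out-group hit, weak in-group
#'   hit).
#' @param seed RNG seed; identical seeds give byte-identical outputs.
#' @return A validated list of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_single_copy = 1000,
                             n_multi_copy = 100,
                             n_species_specific_A = 50,
                             n_species_specific_B = 50,
                             replicates = 3,
                             nb_mean_range = c(1, 1000),
                             nb_dispersion = 0.1,
                             length_range = c(300, 10000),
                             planted_enriched_size = 60,
                             planted_fold = 10,
                             planted_mean_range = c(50, 200),
                             planted_enriched_nonortho = 0,
                             planted_target_size = 50,
                             planted_overlap = 20,
                             planted_target_nonortho = 0,
                             contaminant_fraction = 0.05,
                             seed = 1L) {
  check_scalar_number(n_single_copy, "n_single_copy", min = 0, integerish = TRUE)
  check_scalar_number(n_multi_copy, "n_multi_copy", min = 0, integerish = TRUE)
  check_scalar_number(n_species_specific_A, "n_species_specific_A", min = 0,
                      integerish = TRUE)
  check_scalar_number(n_species_specific_B, "n_species_specific_B", min = 0,
                      integerish = TRUE)
  check_scalar_number(replicates, "replicates", min = 1, integerish = TRUE)
  check_scalar_number(nb_dispersion, "nb_dispersion", min = 1e-12)
  check_scalar_number(planted_fold, "planted_fold", min = 1)
  if (length(planted_mean_range) != 2 || any(planted_mean_range <= 0) ||
      planted_mean_range[1] > planted_mean_range[2]) {
    stop_bad_arg("planted_mean_range", "must be an increasing positive pair")
  }
  check_scalar_number(planted_enriched_size, "planted_enriched_size", min = 0,
                      integerish = TRUE)
  check_scalar_number(planted_enriched_nonortho, "planted_enriched_nonortho",
                      min = 0, max = planted_enriched_size, integerish = TRUE)
  check_scalar_number(planted_target_size, "planted_target_size", min = 0,
                      integerish = TRUE)
  check_scalar_number(planted_target_nonortho, "planted_target_nonortho",
                      min = 0, integerish = TRUE)
  check_scalar_number(planted_overlap, "planted_overlap", min = 0,
                      integerish = TRUE)
  check_scalar_number(contaminant_fraction, "contaminant_fraction",
                      min = 0, max = 1)

  enriched_sc <- planted_enriched_size - planted_enriched_nonortho
  if (enriched_sc > n_single_copy) {
    stop("infeasible config: more single-copy enriched genes than ",
         "single-copy orthogroups", call. = FALSE)
  }
  if (planted_enriched_nonortho > n_species_specific_A) {
    stop("infeasible config: planted_enriched_nonortho exceeds ",
         "n_species_specific_A", call. = FALSE)
  }
  if (planted_target_size > n_single_copy) {
    stop("infeasible config: planted_target_size exceeds n_single_copy",
         call. = FALSE)
  }
  if (planted_target_nonortho > n_species_specific_B) {
    stop("infeasible config: planted_target_nonortho exceeds ",
         "n_species_specific_B", call. = FALSE)
  }
  if (planted_overlap > min(enriched_sc, planted_target_size)) {
    stop("infeasible config: planted_overlap exceeds min(single-copy ",
         "enriched genes, planted_target_size)", call. = FALSE)
  }
  if (planted_target_size - planted_overlap >
      n_single_copy - enriched_sc) {
    stop("infeasible config: not enough non-enriched single-copy ",
         "orthogroups for the target set", call. = FALSE)
  }
  structure(as.list(environment())[c(
    "n_single_copy", "n_multi_copy", "n_species_specific_A",
    "n_species_specific_B", "replicates", "nb_mean_range", "nb_dispersion",
    "length_range", "planted_enriched_size", "planted_fold",
    "planted_mean_range", "planted_enriched_nonortho",
    "planted_target_size", "planted_overlap",
    "planted_target_nonortho", "contaminant_fraction", "seed")],
    class = "synthetic_config")
}

log_uniform <- function(n, range) {
  exp(runif(n, log(range[1]), log(range[2])))
}

#' Generate a synthetic two-species study with known ground truth
#'
#' Draws, under the configured seed: an orthogroup table with the exact
#' configured composition; a species-A count matrix (negative binomial,
#' gene-specific log-uniform baseline means, planted enriched genes with
#' their tissue-group mean multiplied by the planted fold); a species-B
#' target gene list realising the planted overlap exactly; a labelled
#' BLAST best-hit table with the planted contaminant fraction; and the
#' ground truth.
#'
#' @param config a [synthetic_config()].
#' @return list of class `"synthetic_study"` with elements `study`
#'   ([expression_study()], counts), `orthogroups`
#'   (`orthogroup_table`), `target` ([gene_set()], species B), `blast`
#'   (labelled hit data.frame), `subject_groups` (two-column data.frame),
#'   and `truth` (list: `enriched_ids`, `target_ids`,
#'   `overlap_orthogroups`, `enriched_single_copy_orthogroups`,
#'   `contaminant_ids`, `config`).
#' @export
simulate_two_species <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, simulate_two_species_impl(config))
}

simulate_two_species_impl <- function(cfg) {
  # --- orthogroup composition -------------------------------------------
  sc_ids <- sprintf("OG%06d", seq_len(cfg$n_single_copy))
  sc_gene_a <- sprintf("gA_sc%05d", seq_len(cfg$n_single_copy))
  sc_gene_b <- sprintf("gB_sc%05d", seq_len(cfg$n_single_copy))

  mc_ids <- if (cfg$n_multi_copy > 0) {
    sprintf("OG%06d", cfg$n_single_copy + seq_len(cfg$n_multi_copy))
  } else character(0)
  mc_side <- if (cfg$n_multi_copy > 0) {
    sample(c("A", "B"), cfg$n_multi_copy, replace = TRUE)
  } else character(0)
  mc_copies <- if (cfg$n_multi_copy > 0) {
    sample(2:4, cfg$n_multi_copy, replace = TRUE)
  } else integer(0)
  mc_membership <- vector("list", cfg$n_multi_copy)
  mc_genes_a <- character(0)
  for (i in seq_len(cfg$n_multi_copy)) {
    if (mc_side[i] == "A") {
      ga <- sprintf("gA_mc%04d_%d", i, seq_len(mc_copies[i]))
      gb <- sprintf("gB_mc%04d_1", i)
    } else {
      ga <- sprintf("gA_mc%04d_1", i)
      gb <- sprintf("gB_mc%04d_%d", i, seq_len(mc_copies[i]))
    }
    mc_membership[[i]] <- list(ga, gb)
    mc_genes_a <- c(mc_genes_a, ga)
  }

  ss_a <- if (cfg$n_species_specific_A > 0) {
    sprintf("gA_ss%04d", seq_len(cfg$n_species_specific_A))
  } else character(0)
  ss_b <- if (cfg$n_species_specific_B > 0) {
    sprintf("gB_ss%04d", seq_len(cfg$n_species_specific_B))
  } else character(0)
  ss_a_ids <- if (length(ss_a)) {
    sprintf("OG%06d", cfg$n_single_copy + cfg$n_multi_copy + seq_along(ss_a))
  } else character(0)
  ss_b_ids <- if (length(ss_b)) {
    sprintf("OG%06d", cfg$n_single_copy + cfg$n_multi_copy + length(ss_a) +
              seq_along(ss_b))
  } else character(0)

  membership <- c(
    lapply(seq_len(cfg$n_single_copy),
           function(i) list(sc_gene_a[i], sc_gene_b[i])),
    mc_membership,
    lapply(ss_a, function(g) list(g, character(0))),
    lapply(ss_b, function(g) list(character(0), g))
  )
  og_ids <- c(sc_ids, mc_ids, ss_a_ids, ss_b_ids)
  names(membership) <- og_ids
  og_table <- orthogroup_table(og_ids, c("speciesA", "speciesB"), membership)

  # --- planted sets ------------------------------------------------------
  enriched_sc_n <- cfg$planted_enriched_size - cfg$planted_enriched_nonortho
  enriched_sc_idx <- sort(sample.int(cfg$n_single_copy, enriched_sc_n))
  enriched_nonortho <- if (cfg$planted_enriched_nonortho > 0) {
    sort(sample(ss_a, cfg$planted_enriched_nonortho))
  } else character(0)
  enriched_ids <- c(sc_gene_a[enriched_sc_idx], enriched_nonortho)

  overlap_idx <- sort(sample(enriched_sc_idx, cfg$planted_overlap))
  other_pool <- setdiff(seq_len(cfg$n_single_copy), enriched_sc_idx)
  extra_idx <- sort(sample(other_pool,
                           cfg$planted_target_size - cfg$planted_overlap))
  target_sc_idx <- sort(c(overlap_idx, extra_idx))
  target_nonortho <- if (cfg$planted_target_nonortho > 0) {
    sort(sample(ss_b, cfg$planted_target_nonortho))
  } else character(0)
  target_ids <- c(sc_gene_b[target_sc_idx], target_nonortho)

  # --- count matrix (species A) -----------------------------------------
  genes_a <- c(sc_gene_a, mc_genes_a, ss_a)
  n_genes <- length(genes_a)
  lengths <- log_uniform(n_genes, cfg$length_range)
  base_mu <- log_uniform(n_genes, cfg$nb_mean_range)
  enriched_pos <- match(enriched_ids, genes_a)
  base_mu[enriched_pos] <- log_uniform(length(enriched_pos),
                                       cfg$planted_mean_range)
  mu_a <- base_mu
  mu_a[enriched_pos] <- mu_a[enriched_pos] * cfg$planted_fold

  r <- cfg$replicates
  size <- 1 / cfg$nb_dispersion
  counts_a <- matrix(rnbinom(n_genes * r, mu = rep(mu_a, r), size = size),
                     nrow = n_genes)
  counts_b <- matrix(rnbinom(n_genes * r, mu = rep(base_mu, r), size = size),
                     nrow = n_genes)
  values <- cbind(counts_a, counts_b)
  rownames(values) <- genes_a
  colnames(values) <- c(paste0("auricle_", seq_len(r)),
                        paste0("body_", seq_len(r)))
  study <- expression_study(values,
                            sample_groups = rep(c("A", "B"), each = r),
                            lengths = lengths, value_kind = "counts")

  # --- BLAST screen ------------------------------------------------------
  n_q <- n_genes
  n_contam <- round(cfg$contaminant_fraction * n_q)
  contam_idx <- sort(sample.int(n_q, n_contam))
  is_contam <- seq_len(n_q) %in% contam_idx
  # contaminants: weak in-group (>= 1e-2), strong out-group (<= 1e-40);
  # clean queries: strong in-group, out-group hit (if any) always weaker
  e_in <- ifelse(is_contam,
                 10^-runif(n_q, 0, 2),
                 10^-runif(n_q, 5, 100))
  has_out <- !is_contam & runif(n_q) < 0.7
  e_out <- rep(NA_real_, n_q)
  e_out[is_contam] <- 10^-runif(sum(is_contam), 40, 100)
  e_out[has_out] <- pmin(1, e_in[has_out] * 10^runif(sum(has_out), 1, 10))

  rows_in <- data.frame(qseqid = genes_a, sseqid = "ingroup_ref",
                        evalue = e_in, stringsAsFactors = FALSE)
  take_out <- is_contam | has_out
  rows_out <- data.frame(qseqid = genes_a[take_out], sseqid = "outgroup_ref",
                         evalue = e_out[take_out], stringsAsFactors = FALSE)
  hits <- rbind(rows_in, rows_out)
  hits <- hits[order(hits$qseqid, hits$evalue), , drop = FALSE]
  row.names(hits) <- NULL
  hits$pident <- round(runif(nrow(hits), 30, 100), 1)
  hits$bitscore <- round(-log10(hits$evalue + 1e-300) * 2 + 30, 1)
  hits$subject_group <- ifelse(hits$sseqid == "ingroup_ref",
                               "ingroup", "outgroup")
  subject_groups <- data.frame(subject = c("ingroup_ref", "outgroup_ref"),
                               group = c("ingroup", "outgroup"),
                               stringsAsFactors = FALSE)

  truth <- list(
    enriched_ids = enriched_ids,
    target_ids = target_ids,
    overlap_orthogroups = sc_ids[overlap_idx],
    enriched_single_copy_orthogroups = sc_ids[enriched_sc_idx],
    target_single_copy_orthogroups = sc_ids[target_sc_idx],
    contaminant_ids = genes_a[contam_idx],
    config = cfg
  )
  structure(list(study = study, orthogroups = og_table,
                 target = gene_set(target_ids, species = "speciesB",
                                   provenance = "planted target set"),
                 blast = hits, subject_groups = subject_groups,
                 truth = truth),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cfg <- x$truth$config
  cat(sprintf(paste0("synthetic_study: %d single-copy / %d multi-copy ",
                     "orthogroups, %d+%d species-specific genes\n"),
              cfg$n_single_copy, cfg$n_multi_copy,
              cfg$n_species_specific_A, cfg$n_species_specific_B))
  cat(sprintf("  planted: %d enriched (fold %g), %d targets, overlap %d\n",
              cfg$planted_enriched_size, cfg$planted_fold,
              cfg$planted_target_size, cfg$planted_overlap))
  invisible(x)
}

#' Write synthetic inputs in the pipeline's file formats
#'
#' Emits: `counts.tsv` (gene, length, one column per sample),
#' `orthogroups.tsv` (OrthoFinder dialect), `target_genes.txt` (one ID per
#' line), `blast.outfmt6.tsv` (12-column tabular), `subject_groups.tsv`,
#' and `truth.json`. Output is byte-identical for a fixed config.
#'
#' @param sim a [simulate_two_species()] result.
#' @param dir output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_synthetic_inputs <- function(sim, dir) {
  stopifnot(inherits(sim, "synthetic_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)

  st <- sim$study
  counts <- data.frame(gene_id = st$gene_ids,
                       length = sprintf("%.4f", st$lengths),
                       st$values, check.names = FALSE,
                       stringsAsFactors = FALSE)
  write.table(counts, p("counts.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  write_orthogroups(sim$orthogroups, p("orthogroups.tsv"))
  write_gene_set(sim$target, p("target_genes.txt"))

  hits <- sim$blast
  out6 <- data.frame(hits$qseqid, hits$sseqid, hits$pident, 100L, 0L, 0L,
                     1L, 100L, 1L, 100L,
                     formatC(hits$evalue, format = "e", digits = 3),
                     hits$bitscore, stringsAsFactors = FALSE)
  write.table(out6, p("blast.outfmt6.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(sim$subject_groups, p("subject_groups.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)

  truth <- sim$truth
  truth$config <- unclass(truth$config)
  jsonlite::write_json(truth, p("truth.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(c(counts = p("counts.tsv"), orthogroups = p("orthogroups.tsv"),
              target = p("target_genes.txt"),
              blast = p("blast.outfmt6.tsv"),
              subject_groups = p("subject_groups.tsv"),
              truth = p("truth.json")))
}

#' End-to-end recovery check against planted truth
#'
#' Generates a synthetic study, runs the full pipeline on it, and compares
#' the recovered enriched set, projected overlap and Monte Carlo p against
#' the planted ground truth.
#'
#' @param config a [synthetic_config()].
#' @param B Monte Carlo iterations for the overlap test.
#' @param seed seed for the pipeline's Monte Carlo draw (the generator uses
#'   `config$seed`).
#' @param ... further arguments passed to [run_pipeline()] (thresholds).
#' @return list with the pipeline `report`, planted `truth`, and a
#'   `comparison` list: `n_enriched_recovered`, `n_enriched_planted`,
#'   `n_true_positive`, `n_false_positive`, `k_recovered`, `k_planted`,
#'   `p_mc_corrected`.
#' @export
end_to_end_recovery <- function(config, B = 10000, seed = 1L, ...) {
  sim <- simulate_two_species(config)
  report <- run_pipeline(study = sim$study, orthogroups = sim$orthogroups,
                         target = sim$target, B = B, seed = seed, ...)
  enr <- report$enriched$ids
  truth <- sim$truth
  list(
    report = report,
    truth = truth,
    comparison = list(
      n_enriched_recovered = length(enr),
      n_enriched_planted = length(truth$enriched_ids),
      n_true_positive = length(intersect(enr, truth$enriched_ids)),
      n_false_positive = length(setdiff(enr, truth$enriched_ids)),
      k_recovered = report$overlap$k_obs,
      k_planted = length(truth$overlap_orthogroups),
      p_mc_corrected = report$overlap$p_mc_corrected
    )
  )
}
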