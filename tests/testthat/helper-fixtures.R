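# Shared fixtures, built in code at test time.

# Small TPM study with explicit values; groups A,A,A,B,B,B by default.
make_tpm_study <- function(values, groups = NULL) {
  if (is.null(groups)) groups <- rep(c("A", "B"), each = ncol(values) / 2)
  expression_study(values, sample_groups = groups, value_kind = "tpm")
}

# Hand-built differential table for boundary tests on select_enriched().
make_de_table <- function(gene_id, fold_change, p_value,
                          cumulative_tpm = rep(10, length(gene_id)),
                          passed_abundance = rep(TRUE, length(gene_id)),
                          min_cumulative_tpm = 0.1) {
  de <- data.frame(gene_id = gene_id,
                   mean_tpm_A = fold_change, mean_tpm_B = 1,
                   cumulative_tpm = cumulative_tpm,
                   fold_change = fold_change, p_value = p_value,
                   passed_abundance = passed_abundance,
                   stringsAsFactors = FALSE)
  class(de) <- c("de_table", class(de))
  attr(de, "thresholds") <- list(log_pseudocount = 1,
                                 ratio_pseudocount = 0.01,
                                 min_cumulative_tpm = min_cumulative_tpm)
  de
}

# Write an orthogroup file from raw lines and parse it.
parse_og_lines <- function(lines) {
  f <- withr::local_tempfile(fileext = ".tsv",
                             .local_envir = parent.frame())
  writeLines(lines, f)
  read_orthogroups(f)
}

# Exhaustive enumeration oracle for the hypergeometric upper tail:
# walk every size-n subset of 1..N (first K marked) and count overlaps.
enumerate_upper_tail <- function(k, N, K, n) {
  subsets <- utils::combn(N, n)
  overlaps <- colSums(subsets <= K)
  mean(overlaps >= k)
}

# Strong-signal study conditions used by the end-to-end recovery checks.
strong_signal_config <- function(seed = 42) {
  synthetic_config(nb_dispersion = 0.02, replicates = 5, planted_fold = 12,
                   seed = seed)
}
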