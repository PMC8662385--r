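#' Construct an expression study
#'
#' Bundles a genes-by-samples abundance matrix with the per-sample group
#' labels (tissue vs. body) and, when the values are raw counts, the
#' per-gene effective lengths needed for TPM normalisation.
#'
#' @param values numeric matrix, genes in rows, samples in columns; all
#'   values must be finite and non-negative. Row names (or `gene_ids`) give
#'   unique gene identifiers; column names (or `names(sample_groups)`) give
#'   sample names.
#' @param sample_groups character vector mapping every sample to `"A"`
#'   (tissue) or `"B"` (body), named by sample when `values` lacks column
#'   names.
#' @param lengths per-gene effective length in bases (> 0). Required when
#'   `value_kind = "counts"`, ignored for `"tpm"` input.
#' @param value_kind `"counts"` or `"tpm"`.
#' @param gene_ids optional gene identifiers overriding `rownames(values)`.
#'
#' @return An object of class `"expression_study"`: a list with elements
#'   `values`, `gene_ids`, `lengths`, `sample_groups`, `value_kind`.
#' @examples
#' m <- matrix(rpois(12, 50), nrow = 3,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' expression_study(m, sample_groups = c("A", "A", "B", "B"),
#'                  lengths = c(1000, 500, 2000))
#' @export
expression_study <- function(values, sample_groups, lengths = NULL,
                             value_kind = c("counts", "tpm"),
                             gene_ids = NULL) {
  value_kind <- match.arg(value_kind)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_bad_arg("values", "must be a numeric matrix (genes x samples)")
  }
  if (any(!is.finite(values)) || any(values < 0)) {
    stop_bad_arg("values", "must be finite and non-negative")
  }
  gene_ids <- gene_ids %||% rownames(values)
  if (is.null(gene_ids)) {
    stop_bad_arg("gene_ids", "missing: supply rownames(values) or gene_ids")
  }
  gene_ids <- trimws(as.character(gene_ids))
  if (length(gene_ids) != nrow(values)) {
    stop_bad_arg("gene_ids", "length must equal nrow(values)")
  }
  if (anyDuplicated(gene_ids)) {
    stop_bad_arg("gene_ids", "duplicate gene identifiers")
  }
  rownames(values) <- gene_ids

  samples <- colnames(values) %||% names(sample_groups)
  if (is.null(samples)) {
    samples <- paste0("sample", seq_len(ncol(values)))
  }
  colnames(values) <- samples
  if (!is.null(names(sample_groups))) {
    missing <- setdiff(samples, names(sample_groups))
    if (length(missing)) {
      stop_bad_arg("sample_groups",
                   paste("no group for sample(s):",
                         paste(missing, collapse = ", ")))
    }
    sample_groups <- sample_groups[samples]
  }
  sample_groups <- as.character(sample_groups)
  if (length(sample_groups) != ncol(values)) {
    stop_bad_arg("sample_groups", "one group label per sample required")
  }
  if (!all(sample_groups %in% c("A", "B"))) {
    stop_bad_arg("sample_groups", 'labels must be "A" or "B"')
  }
  names(sample_groups) <- samples

  if (value_kind == "counts") {
    if (is.null(lengths)) {
      stop("`lengths` are required for count input (TPM needs them); ",
           "supply lengths or value_kind = \"tpm\"", call. = FALSE)
    }
    lengths <- as.numeric(lengths)
    if (length(lengths) != nrow(values) || any(!is.finite(lengths)) ||
        any(lengths <= 0)) {
      stop_bad_arg("lengths", "must be one finite positive length per gene")
    }
    names(lengths) <- gene_ids
  } else {
    lengths <- NULL
  }

  structure(
    list(values = values, gene_ids = gene_ids, lengths = lengths,
         sample_groups = sample_groups, value_kind = value_kind),
    class = "expression_study"
  )
}

#' @export
print.expression_study <- function(x, ...) {
  cat(sprintf("expression_study: %d genes x %d samples (%s)\n",
              nrow(x$values), ncol(x$values), x$value_kind))
  cat(sprintf("  group A (tissue): %d sample(s); group B (body): %d sample(s)\n",
              sum(x$sample_groups == "A"), sum(x$sample_groups == "B")))
  invisible(x)
}

#' Convert counts to TPM
#'
#' Transcripts per million for each sample column:
#' \deqn{TPM_g = 10^6 \frac{c_g / \ell_g}{\sum_h c_h / \ell_h}}
#' where \eqn{c_g} is the count and \eqn{\ell_g} the effective length of
#' gene \eqn{g}. Every sample column of the result sums to \eqn{10^6}.
#'
#' @param study an [expression_study()] with `value_kind = "counts"`.
#' @return The study with `values` replaced by TPM and
#'   `value_kind = "tpm"`.
#' @export
compute_tpm <- function(study) {
  stopifnot(inherits(study, "expression_study"))
  if (study$value_kind != "counts") {
    stop("compute_tpm() expects count input (value_kind = \"counts\")",
         call. = FALSE)
  }
  rate <- study$values / study$lengths   # reads per base, recycled by row
  totals <- colSums(rate)
  zero <- totals == 0
  if (any(zero)) {
    stop(sprintf("all-zero sample column(s): %s",
                 paste(colnames(study$values)[zero], collapse = ", ")),
         call. = FALSE)
  }
  tpm <- sweep(rate, 2, totals, "/") * 1e6
  study$values <- tpm
  study$value_kind <- "tpm"
  study$lengths <- NULL
  study
}

#' Cumulative-TPM abundance filter
#'
#' Removes genes represented by less than `min_cumulative_tpm` summed over
#' all samples (strict less-than: a gene exactly at the threshold is kept).
#'
#' @param study an [expression_study()] with `value_kind = "tpm"`.
#' @param min_cumulative_tpm removal threshold (default 0.1).
#' @return A [gene_set()] of retained gene identifiers.
#' @export
abundance_filter <- function(study, min_cumulative_tpm = 0.1) {
  stopifnot(inherits(study, "expression_study"))
  if (study$value_kind != "tpm") {
    stop("abundance_filter() expects TPM input; run compute_tpm() first",
         call. = FALSE)
  }
  check_scalar_number(min_cumulative_tpm, "min_cumulative_tpm", min = 0)
  cum <- rowSums(study$values)
  keep <- cum >= min_cumulative_tpm
  gene_set(study$gene_ids[keep], species = "A",
           provenance = sprintf("cumulative TPM >= %g over %d samples",
                                min_cumulative_tpm, ncol(study$values)))
}

#' A labelled gene set
#'
#' @param ids character vector of gene identifiers (deduplicated, trimmed).
#' @param species species label the identifiers belong to.
#' @param provenance free-text description of how the set was derived.
#' @return Object of class `"gene_set"`.
#' @export
gene_set <- function(ids, species = NA_character_, provenance = "") {
  ids <- unique(trimws(as.character(ids)))
  ids <- ids[nzchar(ids)]
  structure(list(ids = ids, species = species, provenance = provenance),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("gene_set: %d ids (species %s)\n", length(x$ids), x$species))
  if (nzchar(x$provenance)) cat(" ", x$provenance, "\n")
  invisible(x)
}

#' @export
length.gene_set <- function(x) length(x$ids)

#' Read a gene-set file
#'
#' One identifier per line; blank lines and `#` comments are ignored.
#'
#' @param path file path.
#' @inheritParams gene_set
#' @return A [gene_set()].
#' @export
read_gene_set <- function(path, species = NA_character_) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  gene_set(lines[nzchar(lines)], species = species,
           provenance = paste("read from", basename(path)))
}

#' Write a gene-set file (one identifier per line)
#'
#' @param x a [gene_set()].
#' @param path output path.
#' @export
write_gene_set <- function(x, path) {
  stopifnot(inherits(x, "gene_set"))
  writeLines(x$ids, path)
  invisible(path)
}

#' Per-gene differential enrichment table
#'
#' For every gene, computes group-mean TPMs, a fold-change (tissue over
#' body, with a pseudocount stabilising the ratio), and a two-sided Welch
#' t-test p-value on `log2(TPM + log_pseudocount)`. Zero-variance groups
#' receive a small variance floor on the log scale so the statistic stays
#' defined; a gene identical in both groups gets p = 1.
#'
#' The abundance filter is evaluated alongside and recorded in the
#' `passed_abundance` column; all genes stay in the table.
#'
#' @param study an [expression_study()] with `value_kind = "tpm"`.
#' @param log_pseudocount pseudocount added before the log2 transform used
#'   by the test (default 1).
#' @param ratio_pseudocount pseudocount added to both group means in the
#'   fold-change ratio (default 0.01; use 0 for the raw ratio of means).
#' @param min_cumulative_tpm threshold for the `passed_abundance` flag.
#' @param var_floor variance floor on the log2 scale (default 1e-8).
#' @param adjust optional multiple-testing adjustment passed to
#'   [stats::p.adjust()] and stored in an extra `p_adjusted` column; the
#'   default `"none"` mirrors filtering on raw p-values.
#' @return A `data.frame` (class `c("de_table", "data.frame")`) with columns
#'   `gene_id`, `mean_tpm_A`, `mean_tpm_B`, `cumulative_tpm`, `fold_change`,
#'   `p_value`, `passed_abundance` (and `p_adjusted` when requested).
#' @export
differential_test <- function(study, log_pseudocount = 1,
                              ratio_pseudocount = 0.01,
                              min_cumulative_tpm = 0.1,
                              var_floor = 1e-8,
                              adjust = "none") {
  stopifnot(inherits(study, "expression_study"))
  if (study$value_kind != "tpm") {
    stop("differential_test() expects TPM input; run compute_tpm() first",
         call. = FALSE)
  }
  check_scalar_number(log_pseudocount, "log_pseudocount", min = 0)
  check_scalar_number(ratio_pseudocount, "ratio_pseudocount", min = 0)
  a <- study$values[, study$sample_groups == "A", drop = FALSE]
  b <- study$values[, study$sample_groups == "B", drop = FALSE]
  na <- ncol(a); nb <- ncol(b)
  if (na == 0 || nb == 0) {
    stop("both groups A and B must have samples", call. = FALSE)
  }
  if (na < 2 && nb < 2) {
    stop("need at least 2 replicates in one group to estimate variance",
         call. = FALSE)
  }

  mean_a <- rowMeans(a)
  mean_b <- rowMeans(b)
  fold <- (mean_a + ratio_pseudocount) / (mean_b + ratio_pseudocount)

  la <- log2(a + log_pseudocount)
  lb <- log2(b + log_pseudocount)
  ma <- rowMeans(la)
  mb <- rowMeans(lb)
  va <- if (na > 1) rowSums((la - ma)^2) / (na - 1) else rep(0, nrow(la))
  vb <- if (nb > 1) rowSums((lb - mb)^2) / (nb - 1) else rep(0, nrow(lb))
  va <- pmax(va, var_floor)
  vb <- pmax(vb, var_floor)

  se2 <- va / na + vb / nb
  tstat <- (ma - mb) / sqrt(se2)
  # Welch-Satterthwaite df; with a single replicate the group's term drops
  # its (n - 1) denominator guard via pmax
  df <- se2^2 / ((va / na)^2 / max(na - 1, 1) + (vb / nb)^2 / max(nb - 1, 1))
  p <- 2 * pt(abs(tstat), df = df, lower.tail = FALSE)
  p[ma == mb & va <= var_floor & vb <= var_floor] <- 1

  cum <- rowSums(study$values)
  out <- data.frame(
    gene_id = study$gene_ids,
    mean_tpm_A = mean_a,
    mean_tpm_B = mean_b,
    cumulative_tpm = cum,
    fold_change = fold,
    p_value = pmin(p, 1),
    passed_abundance = cum >= min_cumulative_tpm,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  if (!identical(adjust, "none")) {
    out$p_adjusted <- stats::p.adjust(out$p_value, method = adjust)
  }
  class(out) <- c("de_table", class(out))
  attr(out, "thresholds") <- list(log_pseudocount = log_pseudocount,
                                  ratio_pseudocount = ratio_pseudocount,
                                  min_cumulative_tpm = min_cumulative_tpm)
  out
}

#' Select tissue-enriched genes
#'
#' Applies the three enrichment criteria to a [differential_test()] table:
#' abundance (cumulative TPM at or above the removal threshold), p-value at
#' or below `max_p`, and fold-change at or above `min_fold`. All three
#' boundaries are inclusive except the abundance removal, which removes
#' strictly-below genes.
#'
#' @param de a `de_table` from [differential_test()].
#' @param min_fold minimum fold-change (default 5; use 2 for the broader
#'   differential-expression regime).
#' @param max_p maximum p-value (default 0.05).
#' @param use_adjusted if `TRUE`, filter on the `p_adjusted` column instead
#'   of raw p (off by default).
#' @return A [gene_set()] with the thresholds recorded in its provenance.
#' @export
select_enriched <- function(de, min_fold = 5, max_p = 0.05,
                            use_adjusted = FALSE) {
  stopifnot(inherits(de, "de_table"))
  check_scalar_number(min_fold, "min_fold", min = 0)
  check_scalar_number(max_p, "max_p", min = 0, max = 1)
  p <- if (use_adjusted) {
    if (is.null(de$p_adjusted)) {
      stop("no p_adjusted column; rerun differential_test(adjust = ...)",
           call. = FALSE)
    }
    de$p_adjusted
  } else {
    de$p_value
  }
  keep <- de$passed_abundance & p <= max_p & de$fold_change >= min_fold
  gene_set(
    de$gene_id[keep], species = "A",
    provenance = sprintf(
      "fold_change >= %g, p %s<= %g, cumulative TPM >= %g (%d of %d genes)",
      min_fold, if (use_adjusted) "(adjusted) " else "", max_p,
      attr(de, "thresholds")$min_cumulative_tpm, sum(keep), nrow(de))
  )
}

#' Read an abundance matrix from TSV
#'
#' First column gene identifiers, header row of sample names. An optional
#' `length` column (any of `length`, `Length`, `effective_length`) is split
#' off as gene lengths.
#'
#' @param path TSV path.
#' @param sample_groups passed to [expression_study()].
#' @param value_kind `"counts"` or `"tpm"`.
#' @return An [expression_study()].
#' @export
read_expression_tsv <- function(path, sample_groups,
                                value_kind = c("counts", "tpm")) {
  value_kind <- match.arg(value_kind)
  tab <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
  ids <- trimws(as.character(tab[[1]]))
  tab <- tab[, -1, drop = FALSE]
  len_col <- intersect(c("length", "Length", "effective_length"),
                       colnames(tab))
  lengths <- NULL
  if (length(len_col)) {
    lengths <- as.numeric(tab[[len_col[1]]])
    tab <- tab[, setdiff(colnames(tab), len_col), drop = FALSE]
  }
  m <- as.matrix(tab)
  storage.mode(m) <- "double"
  rownames(m) <- ids
  expression_study(m, sample_groups = sample_groups, lengths = lengths,
                   value_kind = value_kind)
}
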