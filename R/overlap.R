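#' Exact hypergeometric upper tail
#'
#' \eqn{P(X \ge k)} for \eqn{X \sim} Hypergeometric(N, K, n): the overlap
#' size when n items are drawn without replacement from a universe of N
#' containing K marked items. Evaluated through the log-space-stable
#' distribution function in [stats::phyper()].
#'
#' @param k observed overlap (integer \eqn{\ge 0}).
#' @param N universe size.
#' @param K marked (target-set) items in the universe.
#' @param n drawn (query-set) items.
#' @return The upper-tail probability, in `[0, 1]`.
#' @examples
#' hypergeom_upper_tail(3, N = 10, K = 4, n = 5)  # 66/252
#' @export
hypergeom_upper_tail <- function(k, N, K, n) {
  check_overlap_domain(N, K, n)
  check_scalar_number(k, "k", min = 0, integerish = TRUE)
  if (k <= 0) return(1)
  if (k > min(K, n)) return(0)
  phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}

check_overlap_domain <- function(N, K, n, k_obs = NULL, B = NULL) {
  check_scalar_number(N, "N", min = 0, integerish = TRUE)
  check_scalar_number(K, "K", min = 0, max = N, integerish = TRUE)
  check_scalar_number(n, "n", min = 0, max = N, integerish = TRUE)
  if (!is.null(k_obs)) {
    check_scalar_number(k_obs, "k_obs", min = 0, max = min(K, n),
                        integerish = TRUE)
  }
  if (!is.null(B)) check_scalar_number(B, "B", min = 1, integerish = TRUE)
  invisible(TRUE)
}

#' Monte Carlo overlap test
#'
#' Significance of an observed overlap between two gene (orthogroup) sets
#' under a sampling-without-replacement null. Each of `B` iterations draws
#' `n` distinct items uniformly from a universe of `N` containing `K` marked
#' items and records how many are marked; the p-value is estimated from the
#' number of iterations with overlap at least `k_obs`. The exact
#' hypergeometric upper tail is computed alongside as the analytic
#' counterpart.
#'
#' Two estimators are reported: the raw fraction `exceedances / B`, and the
#' add-one corrected `(exceedances + 1) / (B + 1)`, which is the headline
#' value since a resampling p-value of exactly zero is an artefact of finite
#' `B`.
#'
#' @param N universe size (e.g. number of single-copy orthogroups).
#' @param K size of the marked (target) set within the universe.
#' @param n size of the drawn (query/enriched) set within the universe.
#' @param k_obs observed overlap, `0 <= k_obs <= min(K, n)`.
#' @param B number of Monte Carlo iterations (default 10000).
#' @param seed RNG seed; recorded in the result. Identical seeds give
#'   identical results.
#' @param alternative `"enrichment"` (upper tail, the default) or
#'   `"depletion"` (lower tail, overlap at most `k_obs`).
#' @return Object of class `"overlap_test"` with fields `N`, `K`, `n`,
#'   `k_obs`, `B`, `seed`, `alternative`, `exceedances`, `max_null`,
#'   `p_mc_raw`, `p_mc_corrected`, `p_exact`, and `null_histogram` (named
#'   integer vector of null overlap counts, summing to `B`).
#' @examples
#' overlap_test(N = 8682, K = 88, n = 430, k_obs = 31, B = 1000, seed = 1)
#' @export
overlap_test <- function(N, K, n, k_obs, B = 10000, seed = NULL,
                         alternative = c("enrichment", "depletion")) {
  alternative <- match.arg(alternative)
  check_overlap_domain(N, K, n, k_obs = k_obs, B = B)
  draws <- with_seed(seed, {
    vapply(seq_len(B), function(i) {
      # partial Fisher-Yates draw of n of N indices; first K are the marked
      sum(sample.int(N, n) <= K)
    }, numeric(1))
  })
  hist_counts <- tabulate(draws + 1L, nbins = min(K, n) + 1L)
  names(hist_counts) <- 0:min(K, n)
  exceed <- if (alternative == "enrichment") sum(draws >= k_obs)
            else sum(draws <= k_obs)
  p_exact <- if (alternative == "enrichment") {
    hypergeom_upper_tail(k_obs, N, K, n)
  } else {
    phyper(k_obs, m = K, n = N - K, k = n)
  }
  structure(
    list(N = N, K = K, n = n, k_obs = k_obs, B = B, seed = seed,
         alternative = alternative,
         exceedances = exceed,
         max_null = if (B > 0) max(draws) else NA_integer_,
         p_mc_raw = exceed / B,
         p_mc_corrected = (exceed + 1) / (B + 1),
         p_exact = p_exact,
         null_histogram = hist_counts),
    class = "overlap_test"
  )
}

#' @export
print.overlap_test <- function(x, digits = 4, ...) {
  cat("\tMonte Carlo set-overlap test (sampling without replacement)\n\n")
  cat(sprintf("universe N = %d, target K = %d, query n = %d, observed overlap = %d\n",
              x$N, x$K, x$n, x$k_obs))
  cat(sprintf("null: %d iterations%s, expected overlap %.2f, max null overlap %d\n",
              x$B,
              if (is.null(x$seed)) "" else sprintf(" (seed %s)", x$seed),
              x$n * x$K / x$N, x$max_null))
  dir <- if (x$alternative == "enrichment") ">=" else "<="
  cat(sprintf("iterations with overlap %s %d: %d\n", dir, x$k_obs,
              x$exceedances))
  cat(sprintf("p (Monte Carlo, corrected) = %s; raw = %s; exact tail = %s\n",
              format(x$p_mc_corrected, digits = digits),
              format(x$p_mc_raw, digits = digits),
              format(x$p_exact, digits = digits)))
  invisible(x)
}

#' @export
summary.overlap_test <- function(object, ...) {
  print(object, ...)
  cat("\nnull overlap distribution (nonzero bins):\n")
  nz <- object$null_histogram[object$null_histogram > 0]
  print(nz)
  invisible(object)
}

#' @export
plot.overlap_test <- function(x, ...) {
  h <- x$null_histogram
  bp <- barplot(h / x$B, names.arg = names(h),
                xlab = "null overlap", ylab = "frequency",
                main = "Monte Carlo null overlap distribution", ...)
  if (x$k_obs <= max(as.integer(names(h)))) {
    abline(v = bp[x$k_obs + 1], col = "red", lwd = 2, lty = 2)
  }
  invisible(x)
}

#' Gene-level overlap analysis
#'
#' Convenience wrapper tying the orthology and overlap modules together:
#' projects a species-A enriched gene set and a species-B target gene set
#' into the single-copy orthogroup universe, counts the observed overlap,
#' and runs [overlap_test()] with `N` the number of single-copy
#' orthogroups.
#'
#' @param enriched a [gene_set()] of species-A genes.
#' @param target a [gene_set()] of species-B genes.
#' @param map a [single_copy_map()].
#' @inheritParams overlap_test
#' @return An `"overlap_test"` with extra fields `projected_enriched`,
#'   `projected_target` (orthogroup ID vectors), `overlap_orthogroups`, and
#'   `overlap_pairs` (data.frame of orthogroup, gene_A, gene_B).
#' @export
overlap_analysis <- function(enriched, target, map, B = 10000, seed = NULL,
                             alternative = "enrichment") {
  stopifnot(inherits(map, "single_copy_map"))
  proj_e <- project_gene_set(enriched, map, species = map$species[1])
  proj_t <- project_gene_set(target, map, species = map$species[2])
  shared <- intersect(proj_e, proj_t)
  res <- overlap_test(N = length(map), K = length(proj_t), n = length(proj_e),
                      k_obs = length(shared), B = B, seed = seed,
                      alternative = alternative)
  idx <- match(shared, map$orthogroups)
  res$projected_enriched <- as.character(proj_e)
  res$projected_target <- as.character(proj_t)
  res$overlap_orthogroups <- shared
  res$overlap_pairs <- data.frame(orthogroup = shared,
                                  gene_A = map$gene_A[idx],
                                  gene_B = map$gene_B[idx],
                                  stringsAsFactors = FALSE)
  res$n_unmapped_enriched <- attr(proj_e, "n_unmapped")
  res$n_unmapped_target <- attr(proj_t, "n_unmapped")
  res
}

#' Serialise an overlap test result to JSON
#'
#' Writes every field of the result, both p estimators, and the null
#' histogram; [read_overlap_report()] parses it back to an equivalent
#' object.
#'
#' @param result an `"overlap_test"`.
#' @param path output JSON path.
#' @param labels optional named list of free-text labels stored alongside.
#' @export
write_overlap_report <- function(result, path, labels = NULL) {
  stopifnot(inherits(result, "overlap_test"))
  payload <- unclass(result)
  payload$null_histogram <- as.list(result$null_histogram)
  payload$schema <- "orthoverlap/overlap_test/v1"
  if (!is.null(labels)) payload$labels <- labels
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", dataframe = "rows")
  invisible(path)
}

#' @rdname write_overlap_report
#' @export
read_overlap_report <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$schema, "orthoverlap/overlap_test/v1")) {
    stop("unrecognised overlap report schema", call. = FALSE)
  }
  payload$schema <- NULL
  payload$labels <- NULL
  hist <- unlist(payload$null_histogram)
  payload$null_histogram <- setNames(as.numeric(hist), names(hist))
  if (!is.null(payload$overlap_pairs)) {
    payload$overlap_pairs <- as.data.frame(payload$overlap_pairs,
                                           stringsAsFactors = FALSE)
  }
  structure(payload, class = "overlap_test")
}
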