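#' Read a BLAST tabular (outfmt 6) report
#'
#' Standard 12-column tabular output: qseqid sseqid pident length mismatch
#' gapopen qstart qend sstart send evalue bitscore.
#'
#' @param path path to the tab-separated report (no header).
#' @return A `data.frame` with those columns, types coerced.
#' @export
read_blast_outfmt6 <- function(path) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  tab <- read.delim(path, header = FALSE, sep = "\t",
                    stringsAsFactors = FALSE)
  if (ncol(tab) < 12) {
    stop("expected >= 12 tab-separated columns (BLAST outfmt 6)",
         call. = FALSE)
  }
  tab <- tab[, 1:12]
  colnames(tab) <- cols
  tab$evalue <- as.numeric(tab$evalue)
  if (any(!is.finite(tab$evalue)) || any(tab$evalue < 0)) {
    stop("e-values must be finite and non-negative", call. = FALSE)
  }
  tab
}

#' Label BLAST hits by subject group
#'
#' Attaches an in-group/out-group label to each hit from a subject-to-group
#' map (e.g. in-group = Platyhelminthes subjects, out-group = everything
#' else in the database).
#'
#' @param hits data.frame from [read_blast_outfmt6()] (needs `qseqid`,
#'   `sseqid`, `evalue`).
#' @param subject_groups named character vector or two-column data.frame
#'   (subject, group) mapping subject IDs to `"ingroup"` / `"outgroup"`.
#' @return `hits` with a `subject_group` column.
#' @export
label_blast_hits <- function(hits, subject_groups) {
  if (is.data.frame(subject_groups)) {
    subject_groups <- setNames(as.character(subject_groups[[2]]),
                               as.character(subject_groups[[1]]))
  }
  grp <- unname(subject_groups[hits$sseqid])
  if (anyNA(grp)) {
    stop(sprintf("subject(s) without a group label, e.g. %s",
                 hits$sseqid[is.na(grp)][1]), call. = FALSE)
  }
  if (!all(grp %in% c("ingroup", "outgroup"))) {
    stop('subject groups must be "ingroup" or "outgroup"', call. = FALSE)
  }
  hits$subject_group <- grp
  hits
}

#' Best in-group and out-group hits per query
#'
#' Minimum e-value per query within each subject group. A query with no hit
#' in a group receives the no-hit sentinel e-value of 1, so a transcript
#' with only in-group hits gets a strongly negative alien index.
#'
#' @param hits labelled hit table from [label_blast_hits()] (columns
#'   `qseqid`, `evalue`, `subject_group`).
#' @param queries optional character vector of all screened query IDs;
#'   queries with no hits at all are added with sentinel e-values in both
#'   groups (they count in summary denominators but are never flagged).
#' @param sentinel no-hit e-value (default 1).
#' @return data.frame with `qseqid`, `best_e_ingroup`, `best_e_outgroup`,
#'   `n_hits`.
#' @export
best_hits <- function(hits, queries = NULL, sentinel = 1) {
  if (any(hits$evalue < 0)) stop("negative e-value", call. = FALSE)
  best_in <- tapply(ifelse(hits$subject_group == "ingroup",
                           hits$evalue, Inf),
                    hits$qseqid, min)
  best_out <- tapply(ifelse(hits$subject_group == "outgroup",
                            hits$evalue, Inf),
                     hits$qseqid, min)
  ids <- names(best_in)
  out <- data.frame(
    qseqid = ids,
    best_e_ingroup = ifelse(is.finite(best_in), best_in, sentinel),
    best_e_outgroup = ifelse(is.finite(best_out), best_out, sentinel),
    n_hits = as.integer(table(hits$qseqid)[ids]),
    stringsAsFactors = FALSE, row.names = NULL
  )
  if (!is.null(queries)) {
    missing <- setdiff(queries, ids)
    if (length(missing)) {
      out <- rbind(out, data.frame(qseqid = missing,
                                   best_e_ingroup = sentinel,
                                   best_e_outgroup = sentinel,
                                   n_hits = 0L,
                                   stringsAsFactors = FALSE))
    }
    out <- out[match(queries, out$qseqid), , drop = FALSE]
    row.names(out) <- NULL
  }
  out
}

#' Alien index
#'
#' Contamination / horizontal-transfer score from best homology-search
#' e-values: \deqn{AI = \ln(E_{in} + f) - \ln(E_{out} + f)} with floor
#' \eqn{f} keeping the logarithms finite when a reported e-value is 0. AI
#' is positive when the out-group hit is stronger (smaller e-value) than
#' the in-group hit, and antisymmetric under swapping the two.
#'
#' @param best_e_ingroup,best_e_outgroup best (minimum) e-values per group;
#'   vectorised.
#' @param floor additive floor (default 1e-200).
#' @return Numeric alien index (dimensionless, natural-log scale).
#' @examples
#' alien_index(1e-3, 1e-30)  # 27 * log(10), about 62.2: likely contaminant
#' @export
alien_index <- function(best_e_ingroup, best_e_outgroup, floor = 1e-200) {
  if (any(best_e_ingroup < 0) || any(best_e_outgroup < 0)) {
    stop("e-values must be >= 0", call. = FALSE)
  }
  log(best_e_ingroup + floor) - log(best_e_outgroup + floor)
}

#' Per-query alien-index records
#'
#' @param best data.frame from [best_hits()].
#' @param cutoff flagging cutoff (default 40); a query is `flagged` when
#'   its AI is strictly greater than the cutoff.
#' @param floor passed to [alien_index()].
#' @return data.frame with `qseqid`, `best_e_ingroup`, `best_e_outgroup`,
#'   `AI`, `outgroup_best` (best overall hit is out-group; ties are
#'   `FALSE`), `flagged`.
#' @export
alien_index_records <- function(best, cutoff = 40, floor = 1e-200) {
  ai <- alien_index(best$best_e_ingroup, best$best_e_outgroup, floor = floor)
  data.frame(
    qseqid = best$qseqid,
    best_e_ingroup = best$best_e_ingroup,
    best_e_outgroup = best$best_e_outgroup,
    AI = ai,
    outgroup_best = best$best_e_outgroup < best$best_e_ingroup,
    flagged = ai > cutoff,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Contamination screen summary
#'
#' Fractions, over all screened queries, of transcripts whose best overall
#' hit is out-group and of transcripts whose alien index exceeds the
#' cutoff. Queries with no hits at all stay in the denominator and are
#' never flagged.
#'
#' @param records data.frame from [alien_index_records()].
#' @param cutoff AI cutoff (strict greater-than, default 40).
#' @return list with `n_queries`, `frac_outgroup_best`, `frac_flagged`,
#'   `cutoff`.
#' @export
contamination_summary <- function(records, cutoff = 40) {
  if (!nrow(records)) stop("no records to summarise", call. = FALSE)
  flagged <- records$AI > cutoff
  list(n_queries = nrow(records),
       frac_outgroup_best = mean(records$outgroup_best),
       frac_flagged = mean(flagged),
       cutoff = cutoff)
}
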