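#' Parse an OrthoFinder-style orthogroup table
#'
#' Reads the `Orthogroups.tsv` dialect: a header line
#' `Orthogroup<TAB>speciesA<TAB>speciesB`, then one row per orthogroup with
#' gene lists joined by `", "` (comma-space); an empty cell means no genes
#' for that species. Exactly two species columns are supported.
#'
#' @param path path to the TSV file.
#' @param species optional length-2 character vector overriding the species
#'   labels taken from the header.
#' @return An object of class `"orthogroup_table"`: list with
#'   `orthogroup_ids`, `species` (length 2), and `membership` — a list per
#'   orthogroup of two character vectors of gene IDs, one per species.
#' @export
read_orthogroups <- function(path, species = NULL) {
  lines <- readLines(path)
  if (!length(lines)) stop("empty orthogroup file", call. = FALSE)
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  if (length(header) != 3L || !identical(tolower(header[1]), "orthogroup")) {
    stop("malformed header: expected 'Orthogroup<TAB>speciesA<TAB>speciesB'",
         call. = FALSE)
  }
  sp <- species %||% header[2:3]
  if (length(sp) != 2L || anyDuplicated(sp)) {
    stop_bad_arg("species", "need two distinct species labels")
  }
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  fields <- strsplit(body, "\t", fixed = TRUE)
  og_ids <- vapply(fields, function(f) trimws(f[[1]]), character(1))
  if (anyDuplicated(og_ids)) {
    stop(sprintf("duplicate orthogroup ID: %s",
                 og_ids[duplicated(og_ids)][1]), call. = FALSE)
  }
  split_cell <- function(cell) {
    if (is.na(cell) || !nzchar(trimws(cell))) return(character(0))
    trimws(strsplit(cell, ", ", fixed = TRUE)[[1]])
  }
  membership <- lapply(fields, function(f) {
    list(split_cell(if (length(f) >= 2) f[[2]] else ""),
         split_cell(if (length(f) >= 3) f[[3]] else ""))
  })
  names(membership) <- og_ids
  orthogroup_table(og_ids, sp, membership)
}

# Internal constructor; validates the no-duplicate-gene invariant.
orthogroup_table <- function(orthogroup_ids, species, membership) {
  for (s in 1:2) {
    genes <- unlist(lapply(membership, `[[`, s), use.names = FALSE)
    if (anyDuplicated(genes)) {
      stop(sprintf("gene %s appears in more than one orthogroup (species %s)",
                   genes[duplicated(genes)][1], species[s]), call. = FALSE)
    }
    if (any(!nzchar(genes))) {
      stop("empty gene identifier in orthogroup table", call. = FALSE)
    }
  }
  structure(list(orthogroup_ids = orthogroup_ids, species = species,
                 membership = membership),
            class = "orthogroup_table")
}

#' @export
print.orthogroup_table <- function(x, ...) {
  cat(sprintf("orthogroup_table: %d orthogroups, species %s / %s\n",
              length(x$orthogroup_ids), x$species[1], x$species[2]))
  invisible(x)
}

#' Restrict to single-copy orthogroups
#'
#' Keeps orthogroups with exactly one gene in each of the two species. The
#' resulting map is the universe for the overlap test.
#'
#' @param table an [read_orthogroups()] result.
#' @return An object of class `"single_copy_map"`: list with `orthogroups`,
#'   `species`, `gene_A`, `gene_B` (parallel character vectors) and reverse
#'   lookups `og_of_A`, `og_of_B` (named character vectors gene -> og).
#' @export
single_copy_map <- function(table) {
  stopifnot(inherits(table, "orthogroup_table"))
  counts <- vapply(table$membership,
                   function(m) c(length(m[[1]]), length(m[[2]])),
                   numeric(2))
  keep <- counts[1, ] == 1 & counts[2, ] == 1
  ogs <- table$orthogroup_ids[keep]
  gene_a <- vapply(table$membership[keep], function(m) m[[1]][1], character(1))
  gene_b <- vapply(table$membership[keep], function(m) m[[2]][1], character(1))
  structure(
    list(orthogroups = ogs, species = table$species,
         gene_A = unname(gene_a), gene_B = unname(gene_b),
         og_of_A = setNames(ogs, gene_a),
         og_of_B = setNames(ogs, gene_b)),
    class = "single_copy_map"
  )
}

#' @export
print.single_copy_map <- function(x, ...) {
  cat(sprintf("single_copy_map: %d single-copy orthogroups (%s / %s)\n",
              length(x$orthogroups), x$species[1], x$species[2]))
  invisible(x)
}

#' @export
length.single_copy_map <- function(x) length(x$orthogroups)

#' Project a gene set into orthogroup space
#'
#' Maps each gene of the set to its single-copy orthogroup for the stated
#' species. Genes absent from the map (multi-copy, species-specific, or not
#' in any orthogroup) are dropped; their count is reported in the
#' `n_unmapped` attribute rather than raised as an error, since reduction at
#' this step is expected.
#'
#' @param gene_set a [gene_set()].
#' @param map a [single_copy_map()].
#' @param species which of the map's two species the gene IDs belong to;
#'   defaults to the first.
#' @return Character vector of orthogroup IDs, with attributes `n_unmapped`
#'   (genes without a single-copy orthogroup) and `species`.
#' @export
project_gene_set <- function(gene_set, map, species = NULL) {
  stopifnot(inherits(gene_set, "gene_set"), inherits(map, "single_copy_map"))
  species <- species %||% map$species[1]
  if (!species %in% map$species) {
    stop_bad_arg("species", sprintf("must be one of %s / %s",
                                    map$species[1], map$species[2]))
  }
  lookup <- if (species == map$species[1]) map$og_of_A else map$og_of_B
  hits <- lookup[gene_set$ids]
  mapped <- unname(hits[!is.na(hits)])
  structure(mapped,
            n_unmapped = sum(is.na(hits)),
            species = species)
}

#' Genes of a set of orthogroups
#'
#' Inverse of [project_gene_set()]: the member genes, for one species, of
#' the given single-copy orthogroups.
#'
#' @param orthogroups character vector of orthogroup IDs present in `map`.
#' @inheritParams project_gene_set
#' @return A [gene_set()].
#' @export
genes_of_orthogroups <- function(orthogroups, map, species = NULL) {
  stopifnot(inherits(map, "single_copy_map"))
  species <- species %||% map$species[1]
  idx <- match(orthogroups, map$orthogroups)
  if (anyNA(idx)) {
    stop(sprintf("orthogroup(s) not in map: %s",
                 paste(orthogroups[is.na(idx)][1:min(3, sum(is.na(idx)))],
                       collapse = ", ")), call. = FALSE)
  }
  genes <- if (species == map$species[1]) map$gene_A[idx] else map$gene_B[idx]
  gene_set(genes, species = species,
           provenance = sprintf("members of %d single-copy orthogroups",
                                length(orthogroups)))
}

#' Write an orthogroup table in OrthoFinder dialect
#'
#' @param table an `orthogroup_table`.
#' @param path output TSV path.
#' @export
write_orthogroups <- function(table, path) {
  stopifnot(inherits(table, "orthogroup_table"))
  rows <- vapply(seq_along(table$orthogroup_ids), function(i) {
    m <- table$membership[[i]]
    paste(table$orthogroup_ids[i],
          paste(m[[1]], collapse = ", "),
          paste(m[[2]], collapse = ", "),
          sep = "\t")
  }, character(1))
  writeLines(c(paste("Orthogroup", table$species[1], table$species[2],
                     sep = "\t"), rows), path)
  invisible(path)
}
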