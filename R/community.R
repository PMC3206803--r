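# Occurrence matrices: taxon-by-ecosystem counts of research papers, at
# species and class level, with presence/absence semantics per paper
# (a paper contributes at most 1 to each taxon x ecosystem cell, but may
# contribute to several taxa and several ecosystems).

#' Construct an occurrence matrix
#'
#' @param counts integer matrix, rows = taxa (species taxon_ids or class
#'   names), columns = ecosystem labels.
#' @param level `"species"` or `"class"`.
#' @param paper_totals optional named integer vector: distinct assigned
#'   papers per ecosystem.
#' @return an `occurrence_matrix` object.
#' @export
occurrence_matrix <- function(counts, level = c("species", "class"),
                              paper_totals = NULL) {
  level <- match.arg(level)
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  if (any(counts < 0, na.rm = TRUE)) stop("occurrence counts must be >= 0")
  if (!is.null(paper_totals)) {
    paper_totals <- paper_totals[colnames(counts)]
  }
  structure(list(level = level, counts = counts,
                 paper_totals = paper_totals),
            class = "occurrence_matrix")
}

#' @export
print.occurrence_matrix <- function(x, ...) {
  cat("Occurrence matrix (", x$level, " level): ", nrow(x$counts),
      " taxa x ", ncol(x$counts), " ecosystems\n", sep = "")
  invisible(x)
}

#' Build a taxon-by-ecosystem occurrence matrix from assignments
#'
#' Each cell counts the distinct records assigned both to the taxon and to
#' the ecosystem; `paper_totals` counts distinct records with any retained
#' assignment in the ecosystem.
#'
#' @param assignments named list from [match_corpus()]`$assignments`.
#' @param ecosystem_map named list from [filter_corpus()].
#' @param level `"species"` (taxon_ids) or `"class"` (class names).
#' @return an `occurrence_matrix`.
#' @export
build_matrix <- function(assignments, ecosystem_map,
                         level = c("species", "class")) {
  level <- match.arg(level)
  field <- if (level == "species") "species_set" else "class_set"
  taxa <- sort(unique(unlist(lapply(assignments, `[[`, field),
                             use.names = FALSE)))
  ecosystems <- names(ecosystem_map)
  counts <- matrix(0L, nrow = length(taxa), ncol = length(ecosystems),
                   dimnames = list(taxa, ecosystems))
  paper_totals <- stats::setNames(integer(length(ecosystems)), ecosystems)
  for (e in ecosystems) {
    ids <- intersect(ecosystem_map[[e]], names(assignments))
    paper_totals[e] <- length(ids)
    if (length(ids) == 0) next
    tax <- unlist(lapply(assignments[ids], `[[`, field), use.names = FALSE)
    if (length(tax) == 0) next
    tab <- table(tax)
    counts[names(tab), e] <- as.integer(tab)
  }
  occurrence_matrix(counts, level = level, paper_totals = paper_totals)
}

#' Cross-ecosystem paper totals per taxon
#'
#' Row sums of the occurrence matrix: the "Total" column of a
#' class-by-ecosystem table. Because counts are per-ecosystem paper
#' counts, a paper studied in two ecosystems contributes twice, so a
#' taxon's total may exceed the number of distinct papers mentioning it.
#'
#' @param m an `occurrence_matrix`.
#' @return named integer vector keyed by taxon.
#' @export
class_totals <- function(m) {
  stopifnot(inherits(m, "occurrence_matrix"))
  rowSums(m$counts)
}

#' Per-ecosystem summary counts
#'
#' For each ecosystem: the number of assigned papers, the number of
#' classes with at least one paper, and the number of species with at
#' least one paper -- the "Counts" block of a diversity summary table.
#'
#' @param species_matrix,class_matrix `occurrence_matrix` objects built
#'   from the same assignments at the two levels.
#' @return data frame with columns `ecosystem`, `papers`, `classes`,
#'   `species`.
#' @export
ecosystem_summary <- function(species_matrix, class_matrix) {
  stopifnot(inherits(species_matrix, "occurrence_matrix"),
            species_matrix$level == "species",
            inherits(class_matrix, "occurrence_matrix"),
            class_matrix$level == "class")
  eco <- colnames(class_matrix$counts)
  papers <- if (!is.null(class_matrix$paper_totals)) {
    as.integer(class_matrix$paper_totals[eco])
  } else {
    rep(NA_integer_, length(eco))
  }
  data.frame(
    ecosystem = eco,
    papers = papers,
    classes = as.integer(colSums(class_matrix$counts[, eco, drop = FALSE] > 0)),
    species = as.integer(colSums(species_matrix$counts[, eco, drop = FALSE] > 0)),
    stringsAsFactors = FALSE
  )
}

#' Abundance vector for one ecosystem
#'
#' Extracts the per-taxon paper counts for one ecosystem column (papers as
#' individuals), dropping zero-count taxa -- the input to the diversity
#' battery.
#'
#' @param m an `occurrence_matrix`.
#' @param ecosystem column label.
#' @return named integer vector of positive counts.
#' @export
abundance_vector <- function(m, ecosystem) {
  stopifnot(inherits(m, "occurrence_matrix"))
  if (!ecosystem %in% colnames(m$counts)) {
    stop("unknown ecosystem: ", ecosystem)
  }
  v <- m$counts[, ecosystem]
  v[v > 0]
}

#' Write an occurrence matrix as long-form CSV
#'
#' @param m an `occurrence_matrix`.
#' @param path output file.
#' @return the long-form data frame, invisibly.
#' @export
write_matrix_csv <- function(m, path) {
  stopifnot(inherits(m, "occurrence_matrix"))
  long <- data.frame(
    taxon = rep(rownames(m$counts), times = ncol(m$counts)),
    ecosystem = rep(colnames(m$counts), each = nrow(m$counts)),
    n_papers = as.integer(m$counts),
    stringsAsFactors = FALSE
  )
  long <- long[long$n_papers > 0, , drop = FALSE]
  utils::write.csv(long, path, row.names = FALSE)
  invisible(long)
}
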