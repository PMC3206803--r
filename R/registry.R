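# Taxonomy registry: a WoRMS-style table of valid names and synonyms over a
# fixed 7-rank ladder, with synonym resolution and pairwise taxonomic path
# lengths (the substrate for average taxonomic distinctness).

#' The fixed rank ladder, kingdom to species
#'
#' All registries use exactly these seven ranks; rows missing intermediate
#' ranks are rejected rather than imputed, so every pair of species sits in
#' a tree of consistent depth (average taxonomic distinctness requires
#' this).
#'
#' @export
TAXON_RANKS <- c("kingdom", "phylum", "class", "order", "family",
                 "genus", "species")

#' Read a taxonomy registry from a tab-separated file
#'
#' The file is UTF-8, tab-separated, with a header row:
#' `taxon_id, name, rank, status, accepted_id, kingdom, phylum, class,
#' order, family, genus, species`. Lineage cells below a record's own rank
#' are empty. Records outside the admitted kingdoms are dropped, mirroring
#' the restriction of marine-literature matching to the Animalia, Plantae
#' and Chromista kingdoms.
#'
#' @param path path to the registry file.
#' @param kingdoms character vector of admitted kingdom names.
#' @return a `taxonomy_registry` object.
#' @details Rows violating the structural invariants (unknown rank or
#'   status, wrong word count for the rank, a gap in the lineage) are
#'   rejected with a warning listing their row numbers. A synonym whose
#'   `accepted_id` does not resolve in one hop to a valid record is an
#'   integrity error and aborts the load.
#' @export
read_registry <- function(path,
                          kingdoms = c("Animalia", "Plantae", "Chromista")) {
  if (!file.exists(path)) stop("registry file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", na.strings = NULL,
                          quote = "", fileEncoding = "UTF-8")
  registry_from_df(df, kingdoms = kingdoms)
}

#' Build a taxonomy registry from a data frame
#'
#' Same validation as [read_registry()]; useful for fixtures built in code
#' and for the synthetic generator.
#'
#' @param df data frame with the registry columns (all character).
#' @param kingdoms admitted kingdom names.
#' @return a `taxonomy_registry` object.
#' @export
registry_from_df <- function(df,
                             kingdoms = c("Animalia", "Plantae", "Chromista")) {
  required <- c("taxon_id", "name", "rank", "status", "accepted_id",
                TAXON_RANKS)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("registry schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  }
  df <- df[required]
  for (j in seq_along(df)) df[[j]] <- as.character(df[[j]])
  df[is.na(df)] <- ""

  # kingdom filter first: the registry only ever holds admitted kingdoms
  df <- df[df$kingdom %in% kingdoms, , drop = FALSE]
  if (nrow(df) == 0) {
    return(new_registry(df, kingdoms))
  }

  bad <- validate_rows(df)
  if (length(bad) > 0) {
    warning("rejected ", length(bad), " malformed registry row(s): ",
            paste(utils::head(bad, 20), collapse = ", "),
            if (length(bad) > 20) ", ..." else "")
    df <- df[-bad, , drop = FALSE]
  }
  if (anyDuplicated(df$taxon_id)) {
    stop("registry integrity error: duplicated taxon_id(s): ",
         paste(unique(df$taxon_id[duplicated(df$taxon_id)]), collapse = ", "))
  }

  # synonym chains must terminate in one step at a valid record
  syn <- df$status == "synonym"
  acc <- match(df$accepted_id[syn], df$taxon_id)
  offenders <- df$taxon_id[syn][is.na(acc) | df$status[acc] != "valid"]
  if (length(offenders) > 0) {
    stop("registry integrity error: synonym(s) with unresolvable ",
         "accepted_id: ", paste(offenders, collapse = ", "))
  }
  new_registry(df, kingdoms)
}

new_registry <- function(df, kingdoms) {
  rownames(df) <- df$taxon_id
  norm <- normalize_name(df$name)
  name_index <- split(df$taxon_id, norm)
  structure(list(records = df,
                 name_index = name_index,
                 kingdoms = kingdoms),
            class = "taxonomy_registry")
}

# Row-level structural validation; returns offending row indices.
validate_rows <- function(df) {
  n_words <- lengths(strsplit(trimws(df$name), "[[:space:]]+"))
  rank_i <- match(df$rank, TAXON_RANKS)
  bad_rank <- is.na(rank_i)
  bad_status <- !(df$status %in% c("valid", "synonym"))
  bad_words <- ifelse(df$rank == "species", n_words != 2L, n_words != 1L)
  # lineage contiguous from kingdom down to the record's rank, empty below
  lin <- as.matrix(df[TAXON_RANKS])
  filled <- matrix(nzchar(lin), nrow = nrow(lin))
  bad_lineage <- vapply(seq_len(nrow(df)), function(i) {
    ri <- rank_i[i]
    if (is.na(ri)) return(FALSE) # already flagged
    !all(filled[i, seq_len(ri)]) || any(filled[i, -seq_len(ri)])
  }, logical(1))
  which(bad_rank | bad_status | (bad_words & !bad_rank) | bad_lineage)
}

#' @export
print.taxonomy_registry <- function(x, ...) {
  cat("Taxonomy registry:", nrow(x$records), "records (",
      sum(x$records$status == "synonym"), "synonyms ) across kingdoms:",
      paste(sort(unique(x$records$kingdom)), collapse = ", "), "\n")
  invisible(x)
}

registry_row <- function(registry, taxon_id) {
  i <- match(taxon_id, registry$records$taxon_id)
  if (is.na(i)) stop("unknown taxon_id: ", taxon_id)
  registry$records[i, , drop = FALSE]
}

#' Resolve a taxon to its valid record
#'
#' Identity for valid records; a one-hop jump through `accepted_id` for
#' synonyms. Papers matching a synonymized name are credited to the valid
#' name this resolves to.
#'
#' @param registry a `taxonomy_registry`.
#' @param taxon_id identifier present in the registry.
#' @return a one-row data frame: the valid record.
#' @export
resolve_taxon <- function(registry, taxon_id) {
  rec <- registry_row(registry, taxon_id)
  if (rec$status == "valid") return(rec)
  registry_row(registry, rec$accepted_id)
}

# Vectorized resolution of many ids to valid ids (internal, hot path).
resolve_ids <- function(registry, taxon_ids) {
  i <- match(taxon_ids, registry$records$taxon_id)
  if (anyNA(i)) stop("unknown taxon_id: ",
                     paste(taxon_ids[is.na(i)], collapse = ", "))
  acc <- ifelse(registry$records$status[i] == "valid",
                registry$records$taxon_id[i],
                registry$records$accepted_id[i])
  acc
}

#' Taxonomic path length between two species
#'
#' Number of rank steps from one valid species to another through their
#' lowest shared lineage rank (up then down): 0 for the same species, 2 for
#' congeners, and 12 for species sharing only their kingdom. Species in
#' different kingdoms join at a zero-length root above kingdom, so 12 is
#' the maximum (see the methods vignette).
#'
#' @param registry a `taxonomy_registry`.
#' @param id_a,id_b taxon_ids of valid species records.
#' @return integer step count.
#' @export
taxon_path_length <- function(registry, id_a, id_b) {
  a <- registry_row(registry, id_a)
  b <- registry_row(registry, id_b)
  for (r in list(a, b)) {
    if (r$rank != "species" || r$status != "valid") {
      stop("path length is defined for valid species records only; got ",
           r$taxon_id, " (", r$status, " ", r$rank, ")")
    }
  }
  if (id_a == id_b) return(0L)
  la <- unlist(a[TAXON_RANKS], use.names = FALSE)
  lb <- unlist(b[TAXON_RANKS], use.names = FALSE)
  eq <- la == lb & nzchar(la)
  shared <- if (all(eq)) 7L else which(!cumprod(eq))[1] - 1L
  as.integer(2L * (7L - max(shared, 1L)))
}

#' Pairwise taxonomic distance matrix for a species set
#'
#' Step counts as in [taxon_path_length()], rescaled so the maximum
#' possible path (species sharing only their kingdom) equals 100 -- the
#' conventional scaling for average taxonomic distinctness.
#'
#' @param registry a `taxonomy_registry`.
#' @param species_ids taxon_ids of valid species (duplicates collapsed).
#' @return symmetric numeric matrix in `[0, 100]` with dimnames the ids.
#' @export
taxon_distance_matrix <- function(registry, species_ids) {
  species_ids <- unique(species_ids)
  i <- match(species_ids, registry$records$taxon_id)
  if (anyNA(i)) stop("unknown taxon_id: ",
                     paste(species_ids[is.na(i)], collapse = ", "))
  rec <- registry$records[i, , drop = FALSE]
  if (any(rec$rank != "species" | rec$status != "valid")) {
    stop("distance matrix is defined for valid species records only")
  }
  n <- length(species_ids)
  lin <- as.matrix(rec[TAXON_RANKS])
  # shared depth for each pair: deepest rank down to which all lineage
  # names agree (cumulative, so homonymous names deeper down cannot fake
  # agreement); clamped at kingdom so cross-kingdom pairs take the maximum
  depth <- matrix(0L, n, n)
  agree <- matrix(TRUE, n, n)
  for (k in seq_len(7L)) {
    agree <- agree & outer(lin[, k], lin[, k], "==")
    depth <- depth + agree
  }
  steps <- 2L * (7L - pmax(depth, 1L))
  diag(steps) <- 0L
  d <- steps / 12 * 100
  dimnames(d) <- list(species_ids, species_ids)
  d
}
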