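# End-to-end convenience: corpus -> ecosystem filter -> name matching ->
# occurrence matrices, the sequence every analysis in this package starts
# from.

#' Run the full literature-mining pipeline
#'
#' Filters records into ecosystems by phrase queries, matches and assigns
#' taxonomic names against the registry, and builds species- and
#' class-level occurrence matrices.
#'
#' @param records data frame from [read_ris()].
#' @param registry a `taxonomy_registry`.
#' @param queries named phrase lists (see [default_queries()]).
#' @param policy homonym policy, see [assign_record()].
#' @return list with `ecosystem_map`, `assignments`, `audit`,
#'   `species_matrix`, `class_matrix`, and `summary` (per-ecosystem
#'   papers/classes/species counts).
#' @export
#' @examples
#' cfg <- synth_config(n_phyla = 3, n_classes = 5, n_species = 25,
#'                     n_records = 40, seed = 42)
#' reg <- make_registry(cfg)
#' corp <- make_corpus(cfg, reg)
#' res <- run_pipeline(read_ris(corp$path), reg$registry)
#' res$summary
run_pipeline <- function(records, registry, queries = default_queries(),
                         policy = c("exclude", "all")) {
  policy <- match.arg(policy)
  ecosystem_map <- filter_corpus(records, queries)
  matched <- match_corpus(records, registry, policy = policy)
  species_matrix <- build_matrix(matched$assignments, ecosystem_map,
                                 level = "species")
  class_matrix <- build_matrix(matched$assignments, ecosystem_map,
                               level = "class")
  list(ecosystem_map = ecosystem_map,
       assignments = matched$assignments,
       audit = matched$audit,
       species_matrix = species_matrix,
       class_matrix = class_matrix,
       summary = ecosystem_summary(species_matrix, class_matrix))
}

#' Named-species richness per class in a registry
#'
#' Counts valid species records per class -- the "globally named species"
#' predictor of the effort-versus-richness model -- along with each
#' class's phylum.
#'
#' @param registry a `taxonomy_registry`.
#' @return data frame with `class`, `phylum`, `n_species_worms`.
#' @export
class_richness <- function(registry) {
  rec <- registry$records
  sp <- rec[rec$rank == "species" & rec$status == "valid", , drop = FALSE]
  cls <- rec[rec$rank == "class" & rec$status == "valid", , drop = FALSE]
  counts <- table(sp$class)
  out <- data.frame(class = cls$name, phylum = cls$phylum,
                    n_species_worms = as.integer(counts[cls$name]),
                    stringsAsFactors = FALSE)
  out$n_species_worms[is.na(out$n_species_worms)] <- 0L
  rownames(out) <- NULL
  out[order(out$class), , drop = FALSE]
}

#' Assemble the per-class effort table
#'
#' Joins cross-ecosystem paper totals from a class-level occurrence
#' matrix with registry species richness, ready for
#' [fit_effort_richness()]. Classes present in the registry but absent
#' from the literature get `n_papers = 0` (excluded from the regression,
#' reported as unstudied).
#'
#' @param class_matrix class-level `occurrence_matrix`.
#' @param registry a `taxonomy_registry`.
#' @return data frame with `class`, `phylum`, `n_papers`,
#'   `n_species_worms`.
#' @export
effort_table <- function(class_matrix, registry) {
  rich <- class_richness(registry)
  totals <- class_totals(class_matrix)
  rich$n_papers <- as.integer(totals[rich$class])
  rich$n_papers[is.na(rich$n_papers)] <- 0L
  rich[c("class", "phylum", "n_papers", "n_species_worms")]
}
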