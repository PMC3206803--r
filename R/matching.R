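# Taxonomic name matching: extract all unique one- and two-word sequences
# from each record's searchable text and match them against the registry,
# resolving synonyms to valid names and flagging homonyms.

#' Extract unique uni- and bigrams from a record's searchable text
#'
#' Tokenizes the title, each author keyword, and the abstract (lowercase,
#' hyphens split, edge punctuation stripped) and returns the union of all
#' single tokens and adjacent token pairs. Bigrams never span
#' sentence-final punctuation or keyword boundaries.
#'
#' @param title,abstract text fields (scalars; may be empty).
#' @param keywords character vector of author keywords.
#' @return character vector of unique normalized 1- and 2-word strings.
#' @export
#' @examples
#' extract_ngrams("Acropora grows fast.", character(0), "")
extract_ngrams <- function(title, keywords = character(0), abstract = "") {
  sents <- record_sentences(title, keywords, abstract)
  if (length(sents) == 0) return(character(0))
  grams <- lapply(sents, function(toks) {
    n <- length(toks)
    bi <- if (n >= 2) paste(toks[-n], toks[-1]) else character(0)
    c(toks, bi)
  })
  unique(unlist(grams, use.names = FALSE))
}

#' Match n-grams against a taxonomy registry
#'
#' Each n-gram found in the registry's name index yields one row per
#' distinct valid taxon it resolves to (synonyms are resolved to their
#' accepted name first). A normalized name resolving to more than one
#' valid taxon is a homonym: all its rows carry `ambiguous = TRUE` and are
#' excluded from record assignment under the default policy.
#'
#' @param ngrams character vector from [extract_ngrams()].
#' @param registry a `taxonomy_registry`.
#' @return data frame: `matched_string`, `taxon_id` (valid), `name`
#'   (valid name), `rank`, `class`, `phylum`, `kingdom`, `ambiguous`.
#' @export
match_ngrams <- function(ngrams, registry) {
  empty <- data.frame(matched_string = character(), taxon_id = character(),
                      name = character(), rank = character(),
                      class = character(), phylum = character(),
                      kingdom = character(), ambiguous = logical(),
                      stringsAsFactors = FALSE)
  if (length(ngrams) == 0) return(empty)
  hits <- intersect(ngrams, names(registry$name_index))
  if (length(hits) == 0) return(empty)
  rows <- lapply(hits, function(g) {
    valid_ids <- unique(resolve_ids(registry, registry$name_index[[g]]))
    i <- match(valid_ids, registry$records$taxon_id)
    data.frame(matched_string = g,
               taxon_id = valid_ids,
               name = registry$records$name[i],
               rank = registry$records$rank[i],
               class = registry$records$class[i],
               phylum = registry$records$phylum[i],
               kingdom = registry$records$kingdom[i],
               ambiguous = length(valid_ids) > 1L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Reduce one record's matches to a taxonomic assignment
#'
#' Applies the homonym policy, lets a two-word species match supersede its
#' embedded one-word genus match (the genus word is counted once, at
#' species rank), and keeps the record only if some retained match
#' resolves to phylum level or better (phylum or any lower rank).
#'
#' @param matches data frame from [match_ngrams()] for one record.
#' @param registry a `taxonomy_registry`.
#' @param policy `"exclude"` drops homonymous (ambiguous) matches to
#'   protect precision (the default); `"all"` assigns them to every
#'   candidate taxon.
#' @return a list with `species_set` (valid species taxon_ids),
#'   `class_set` (class names implied by matches at class rank or below),
#'   and `phylum_or_better = TRUE`; or `NULL` when the record fails the
#'   phylum-or-better rule.
#' @export
assign_record <- function(matches, registry, policy = c("exclude", "all")) {
  policy <- match.arg(policy)
  if (policy == "exclude") {
    matches <- matches[!matches$ambiguous, , drop = FALSE]
  }
  if (nrow(matches) == 0) return(NULL)

  # a species match covers the genus unigram embedded in its binomial
  sp <- matches$rank == "species"
  if (any(sp)) {
    covered_genera <- unique(vapply(strsplit(matches$matched_string[sp],
                                             " ", fixed = TRUE),
                                    `[`, "", 1L))
    drop <- matches$rank == "genus" &
      matches$matched_string %in% covered_genera
    matches <- matches[!drop, , drop = FALSE]
  }

  below_kingdom <- matches$rank != "kingdom"
  if (!any(below_kingdom)) return(NULL)

  class_or_below <- matches$rank %in% c("class", "order", "family",
                                        "genus", "species")
  list(species_set = unique(matches$taxon_id[matches$rank == "species"]),
       class_set = unique(matches$class[class_or_below &
                                          nzchar(matches$class)]),
       phylum_or_better = TRUE)
}

#' Match and assign a whole corpus
#'
#' Runs [extract_ngrams()], [match_ngrams()] and [assign_record()] over
#' every record and collects an audit trail of raw matches.
#'
#' @param records data frame from [read_ris()].
#' @param registry a `taxonomy_registry`.
#' @param policy homonym policy, see [assign_record()].
#' @return list with `assignments` (named list of per-record assignments,
#'   records failing the phylum-or-better rule omitted) and `audit` (one
#'   data frame of all matches, with `record_id`).
#' @export
match_corpus <- function(records, registry, policy = c("exclude", "all")) {
  policy <- match.arg(policy)
  assignments <- list()
  audit <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    ngrams <- extract_ngrams(records$title[i], records$keywords[[i]],
                             records$abstract[i])
    m <- match_ngrams(ngrams, registry)
    if (nrow(m) > 0) {
      audit[[i]] <- cbind(record_id = records$record_id[i], m,
                          stringsAsFactors = FALSE)
    }
    a <- assign_record(m, registry, policy = policy)
    if (!is.null(a)) assignments[[records$record_id[i]]] <- a
  }
  audit <- audit[!vapply(audit, is.null, TRUE)]
  audit <- if (length(audit) > 0) {
    out <- do.call(rbind, audit)
    rownames(out) <- NULL
    out
  } else {
    data.frame(record_id = character(), matched_string = character(),
               taxon_id = character(), name = character(),
               rank = character(), class = character(),
               phylum = character(), kingdom = character(),
               ambiguous = logical(), stringsAsFactors = FALSE)
  }
  list(assignments = assignments, audit = audit)
}
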