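# Ground-truthed synthetic data: a balanced random taxonomy over the
# 7-rank ladder with pseudo-Latin names, and a bibliographic corpus with
# ecosystem phrases and taxon mentions planted at known rates, plus a
# plant log recording exact ground truth for every stage of the pipeline.

# Filler lexicon for template prose. Reserved: generated taxon names are
# guaranteed never to collide with these words (or with ecosystem phrase
# words), so the only name/prose collisions are deliberately planted
# homonyms.
FILLER_WORDS <- c(
  "the", "of", "and", "in", "study", "effects", "dynamics", "growth",
  "patterns", "habitat", "community", "analysis", "along", "gradient",
  "temperate", "tropical", "survey", "during", "seasonal", "responses",
  "between", "among", "with", "from", "observed", "measured", "results",
  "suggest", "strong", "weak", "increase", "decline", "populations",
  "assemblage", "structure", "function", "role", "benthic", "shallow",
  "coastal", "waters", "sites", "samples", "data", "field", "experiment",
  "model", "spatial", "temporal", "variation", "diversity", "abundance",
  "richness", "recruitment", "settlement", "larval", "juvenile", "adult",
  "nutrient", "light", "temperature", "salinity", "depth", "exposure",
  "predation", "grazing", "competition", "disturbance", "recovery")

ECOSYSTEM_WORDS <- c("coral", "reef", "reefs", "kelp", "forest", "forests",
                     "mangrove", "seagrass", "bed", "beds", "meadow",
                     "meadows")

KINGDOM_POOL <- c("Animalia", "Plantae", "Chromista", "Fungi", "Protozoa")

#' Configuration for the synthetic registry and corpus
#'
#' Defaults emulate the study conditions at desk scale: a three-kingdom
#' registry, a 1,000-record corpus over the 1957--2009 window, ecosystem
#' plant rates proportional to the four literatures' relative sizes, and
#' per-class mention rates drawn log-normally so paper counts have the
#' heavy right tail seen in real class-level tables.
#'
#' @param n_kingdoms,n_phyla,n_classes,n_species tree shape (each rank
#'   nested in the previous; orders, families and genera are generated
#'   automatically between class and species).
#' @param synonym_rate fraction of species carrying one synonym record.
#' @param homonym_count planted cross-kingdom duplicate genus names.
#' @param n_records corpus size.
#' @param ecosystem_rates named per-ecosystem probabilities that a record
#'   gets that ecosystem's phrase planted.
#' @param mention_rates optional named per-class probabilities that a
#'   record mentions a member species; `NULL` draws them log-normally.
#' @param homonym_mention_rate per-record probability of planting a bare
#'   homonymous genus name (only when `homonym_count > 0`).
#' @param kwplus_rate per-record probability that an otherwise unassigned
#'   record carries an ecosystem phrase only in its database-generated
#'   keyword field (which the reader ignores, so the filter drops it).
#' @param year_range publication-year window.
#' @param seed integer seed; registry and corpus are deterministic given
#'   the config.
#' @return a `synth_config` list.
#' @export
synth_config <- function(n_kingdoms = 3L, n_phyla = 6L, n_classes = 20L,
                         n_species = 200L, synonym_rate = 0.15,
                         homonym_count = 0L, n_records = 1000L,
                         ecosystem_rates = c(coral_reef = 0.50,
                                             kelp_forest = 0.05,
                                             mangrove_forest = 0.12,
                                             seagrass_bed = 0.17),
                         mention_rates = NULL,
                         homonym_mention_rate = 0.05,
                         kwplus_rate = 0.03,
                         year_range = c(1957L, 2009L),
                         seed = 1L) {
  cfg <- list(n_kingdoms = as.integer(n_kingdoms),
              n_phyla = as.integer(n_phyla),
              n_classes = as.integer(n_classes),
              n_species = as.integer(n_species),
              synonym_rate = synonym_rate,
              homonym_count = as.integer(homonym_count),
              n_records = as.integer(n_records),
              ecosystem_rates = ecosystem_rates,
              mention_rates = mention_rates,
              homonym_mention_rate = homonym_mention_rate,
              kwplus_rate = kwplus_rate,
              year_range = as.integer(year_range),
              seed = as.integer(seed))
  with(cfg, {
    if (n_kingdoms < 1 || n_kingdoms > length(KINGDOM_POOL)) {
      stop("n_kingdoms must be in 1..", length(KINGDOM_POOL))
    }
    if (n_phyla < n_kingdoms || n_classes < n_phyla ||
        n_species < n_classes) {
      stop("impossible tree shape: need kingdoms <= phyla <= classes ",
           "<= species")
    }
    rates <- c(synonym_rate, homonym_mention_rate, kwplus_rate,
               ecosystem_rates, mention_rates)
    if (any(rates < 0 | rates > 1)) stop("all rates must lie in [0, 1]")
    if (homonym_count > 0 && n_kingdoms < 2) {
      stop("planted homonyms require >= 2 kingdoms")
    }
  })
  structure(cfg, class = "synth_config")
}

# Pseudo-Latin word generator: consonant-vowel syllables plus a Latin-ish
# ending; rejects collisions with reserved words and previous draws.
make_words <- function(n, used, endings = c("us", "a", "is", "um", "ex")) {
  cons <- c("b", "c", "d", "f", "g", "l", "m", "n", "p", "r", "s", "t",
            "v", "z", "th", "ch", "br", "cr", "pl", "str")
  vow <- c("a", "e", "i", "o", "u", "ae")
  reserved <- c(used, FILLER_WORDS, ECOSYSTEM_WORDS,
                tolower(KINGDOM_POOL))
  out <- character(0)
  guard <- 0L
  while (length(out) < n) {
    guard <- guard + 1L
    if (guard > 200000L) stop("name generator exhausted")
    k <- sample(2:3, 1)
    w <- paste0(paste0(sample(cons, k, replace = TRUE),
                       sample(vow, k, replace = TRUE), collapse = ""),
                sample(endings, 1))
    if (!(w %in% reserved) && !(w %in% out)) out <- c(out, w)
  }
  out
}

cap <- function(x) paste0(toupper(substring(x, 1, 1)), substring(x, 2))

#' Generate a synthetic taxonomy registry
#'
#' Builds a balanced random tree over the 7-rank ladder with pseudo-Latin
#' names (distinct by construction except planted homonyms), assigns
#' species to classes with log-normal weights (heavy right tail), emits
#' synonym records per `synonym_rate`, and optionally renames genera in a
#' second kingdom to plant cross-kingdom homonyms. Deterministic per
#' `config$seed`; writes a registry file when `path` is given.
#'
#' @param config a [synth_config()].
#' @param path optional path for the tab-separated registry file.
#' @return list with `registry` (a `taxonomy_registry` over all generated
#'   kingdoms), `table` (the raw data frame), `homonym_names`, and
#'   `path` (or `NULL`).
#' @export
make_registry <- function(config, path = NULL) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  used <- character(0)
  kingdom_names <- KINGDOM_POOL[seq_len(config$n_kingdoms)]

  phylum_names <- cap(make_words(config$n_phyla, used))
  used <- c(used, tolower(phylum_names))
  phylum_kingdom <- kingdom_names[rep_len(seq_len(config$n_kingdoms),
                                          config$n_phyla)]

  class_names <- cap(make_words(config$n_classes, used))
  used <- c(used, tolower(class_names))
  class_phylum <- rep_len(seq_len(config$n_phyla), config$n_classes)

  # species per class: every class gets one, the rest follow log-normal
  # weights so a few classes dominate (as in real class-level tables)
  w <- stats::rlnorm(config$n_classes, meanlog = 0, sdlog = 1.2)
  extra <- config$n_species - config$n_classes
  sp_class <- c(seq_len(config$n_classes),
                sample(seq_len(config$n_classes), extra, replace = TRUE,
                       prob = w))
  sp_class <- sort(sp_class)

  rows <- list()
  add_row <- function(taxon_id, name, rank, status, accepted_id, lineage) {
    full <- stats::setNames(rep("", 7L), TAXON_RANKS)
    full[names(lineage)] <- lineage
    rows[[length(rows) + 1L]] <<- data.frame(
      taxon_id = taxon_id, name = name, rank = rank, status = status,
      accepted_id = accepted_id, t(full), stringsAsFactors = FALSE)
  }

  for (k in seq_len(config$n_kingdoms)) {
    add_row(paste0("K", k), kingdom_names[k], "kingdom", "valid",
            paste0("K", k), c(kingdom = kingdom_names[k]))
  }
  for (p in seq_len(config$n_phyla)) {
    add_row(paste0("P", p), phylum_names[p], "phylum", "valid",
            paste0("P", p),
            c(kingdom = phylum_kingdom[p], phylum = phylum_names[p]))
  }
  class_lineage <- vector("list", config$n_classes)
  for (cl in seq_len(config$n_classes)) {
    p <- class_phylum[cl]
    class_lineage[[cl]] <- c(kingdom = phylum_kingdom[p],
                             phylum = phylum_names[p],
                             class = class_names[cl])
    add_row(paste0("C", cl), class_names[cl], "class", "valid",
            paste0("C", cl), class_lineage[[cl]])
  }

  # orders, families, genera generated bottom-up within each class
  genus_of_species <- character(config$n_species)
  species_names <- character(config$n_species)
  sp_lineage <- vector("list", config$n_species)
  o_id <- f_id <- g_id <- 0L
  genus_names_all <- character(0)
  genus_ids_all <- character(0)
  genus_kingdom_all <- character(0)
  genus_lineage_all <- list()
  for (cl in seq_len(config$n_classes)) {
    sp_idx <- which(sp_class == cl)
    n_sp <- length(sp_idx)
    n_gen <- max(1L, ceiling(n_sp / stats::runif(1, 1.8, 3)))
    n_fam <- max(1L, ceiling(n_gen / 2))
    n_ord <- max(1L, ceiling(n_fam / 2))
    ord_names <- cap(make_words(n_ord, used)); used <- c(used, tolower(ord_names))
    fam_names <- cap(make_words(n_fam, used)); used <- c(used, tolower(fam_names))
    gen_names <- cap(make_words(n_gen, used)); used <- c(used, tolower(gen_names))
    fam_ord <- rep_len(seq_len(n_ord), n_fam)
    gen_fam <- rep_len(seq_len(n_fam), n_gen)
    sp_gen <- sample(rep_len(seq_len(n_gen), n_sp))
    for (o in seq_len(n_ord)) {
      o_id <- o_id + 1L
      add_row(paste0("O", o_id), ord_names[o], "order", "valid",
              paste0("O", o_id),
              c(class_lineage[[cl]], order = ord_names[o]))
    }
    ord_base <- o_id - n_ord
    for (f in seq_len(n_fam)) {
      f_id <- f_id + 1L
      add_row(paste0("F", f_id), fam_names[f], "family", "valid",
              paste0("F", f_id),
              c(class_lineage[[cl]], order = ord_names[fam_ord[f]],
                family = fam_names[f]))
    }
    fam_base <- f_id - n_fam
    for (g in seq_len(n_gen)) {
      g_id <- g_id + 1L
      lin <- c(class_lineage[[cl]],
               order = ord_names[fam_ord[gen_fam[g]]],
               family = fam_names[gen_fam[g]], genus = gen_names[g])
      add_row(paste0("G", g_id), gen_names[g], "genus", "valid",
              paste0("G", g_id), lin)
      genus_names_all <- c(genus_names_all, gen_names[g])
      genus_ids_all <- c(genus_ids_all, paste0("G", g_id))
      genus_kingdom_all <- c(genus_kingdom_all, phylum_kingdom[class_phylum[cl]])
      genus_lineage_all[[length(genus_lineage_all) + 1L]] <- lin
    }
    gen_base <- g_id - n_gen
    for (j in seq_along(sp_idx)) {
      s <- sp_idx[j]
      genus_of_species[s] <- genus_ids_all[gen_base + sp_gen[j]]
      sp_lineage[[s]] <- genus_lineage_all[[gen_base + sp_gen[j]]]
    }
  }

  epithets <- make_words(config$n_species, used, endings = c("i", "ae", "ensis", "icus", "osa"))
  used <- c(used, epithets)
  gi <- match(genus_of_species, genus_ids_all)
  species_names <- paste(genus_names_all[gi], epithets)
  for (s in seq_len(config$n_species)) {
    add_row(paste0("S", s), species_names[s], "species", "valid",
            paste0("S", s),
            c(sp_lineage[[s]], species = species_names[s]))
  }

  # synonyms: a fresh two-word name pointing at the valid species
  has_syn <- stats::runif(config$n_species) < config$synonym_rate
  syn_of <- which(has_syn)
  if (length(syn_of) > 0) {
    syn_genus <- cap(make_words(length(syn_of), used))
    used <- c(used, tolower(syn_genus))
    syn_epi <- make_words(length(syn_of), used, endings = c("i", "ae", "ensis"))
    used <- c(used, syn_epi)
    for (j in seq_along(syn_of)) {
      s <- syn_of[j]
      syn_name <- paste(syn_genus[j], syn_epi[j])
      add_row(paste0("Y", j), syn_name, "species", "synonym",
              paste0("S", s),
              c(sp_lineage[[s]], species = syn_name))
    }
  }

  df <- do.call(rbind, rows)
  rownames(df) <- NULL

  # planted homonyms: rename a genus in another kingdom to an existing
  # genus name, so one normalized name maps to two valid taxa
  homonym_names <- character(0)
  if (config$homonym_count > 0) {
    k1 <- genus_kingdom_all == kingdom_names[1]
    donors <- genus_ids_all[k1]
    victims <- genus_ids_all[!k1]
    n_h <- min(config$homonym_count, length(donors), length(victims))
    if (n_h < config$homonym_count) {
      stop("not enough genera across kingdoms to plant ",
           config$homonym_count, " homonyms")
    }
    don <- sample(donors, n_h)
    vic <- sample(victims, n_h)
    for (j in seq_len(n_h)) {
      new_name <- df$name[df$taxon_id == don[j]]
      old_name <- df$name[df$taxon_id == vic[j]]
      df$name[df$taxon_id == vic[j]] <- new_name
      # lineage genus cells and member species binomials follow the rename
      df$genus[df$genus == old_name] <- new_name
      member <- df$rank == "species" & df$status == "valid" &
        startsWith(df$name, paste0(old_name, " "))
      df$name[member] <- sub(paste0("^", old_name), new_name, df$name[member])
      df$species[member] <- df$name[member]
      homonym_names <- c(homonym_names, new_name)
    }
  }

  if (!is.null(path)) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
  }
  list(registry = registry_from_df(df, kingdoms = kingdom_names),
       table = df, homonym_names = homonym_names, path = path)
}

sentence <- function(words) {
  paste0(paste(words, collapse = " "), ".")
}

filler <- function(n) sample(FILLER_WORDS, n, replace = TRUE)

#' Generate a synthetic bibliographic corpus with a plant log
#'
#' Emits `n_records` tagged records with template prose. Ecosystem phrases
#' are planted per `ecosystem_rates` into title, author keywords, or
#' abstract; taxon mentions are planted per class per `mention_rates`
#' (surface form: the valid binomial, or a synonym when one exists, with
#' equal odds); bare homonymous genus names are planted per
#' `homonym_mention_rate`. A small fraction of otherwise unassigned
#' records carry a phrase only in the database-keyword (`ID`) field,
#' which [read_ris()] ignores. The plant log records exact ground truth.
#' Deterministic per `config$seed` (offset so registry and corpus draws
#' are independent).
#'
#' @param config a [synth_config()].
#' @param reg result of [make_registry()] for the same config.
#' @param path output path for the RIS file (default: a temp file).
#' @return list with `path`, `ecosystem_log` (record_id, ecosystem),
#'   `mention_log` (record_id, taxon_id, surface, rank, class,
#'   ambiguous; homonym plants have one row per candidate taxon),
#'   `mention_rates` (the per-class rates used), and `kwplus_records`.
#' @export
make_corpus <- function(config, reg, path = tempfile(fileext = ".ris")) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed + 10000L)
  rec_tab <- reg$registry$records
  species <- rec_tab[rec_tab$rank == "species" & rec_tab$status == "valid", ]
  synonyms <- rec_tab[rec_tab$status == "synonym", ]
  syn_by_accepted <- split(synonyms$name, synonyms$accepted_id)
  classes <- sort(unique(species$class))

  mention_rates <- config$mention_rates
  if (is.null(mention_rates)) {
    mention_rates <- stats::setNames(
      pmin(stats::rlnorm(length(classes), meanlog = log(0.04), sdlog = 1.1),
           0.5),
      classes)
  } else {
    if (is.null(names(mention_rates)) ||
        !all(classes %in% names(mention_rates))) {
      stop("mention_rates must be named by class and cover every class")
    }
    mention_rates <- mention_rates[classes]
  }
  sp_by_class <- split(seq_len(nrow(species)), species$class)

  homonyms <- reg$homonym_names
  hom_candidates <- if (length(homonyms) > 0) {
    lapply(stats::setNames(homonyms, homonyms), function(nm) {
      ids <- rec_tab$taxon_id[rec_tab$name == nm & rec_tab$rank == "genus"]
      rec_tab[match(ids, rec_tab$taxon_id), c("taxon_id", "class")]
    })
  } else {
    list()
  }

  queries <- default_queries()
  eco_labels <- names(config$ecosystem_rates)
  bad_eco <- setdiff(eco_labels, names(queries))
  if (length(bad_eco) > 0) stop("no phrase query for ecosystem(s): ",
                                paste(bad_eco, collapse = ", "))

  lines <- character(0)
  eco_log <- list()
  men_log <- list()
  kwplus_records <- character(0)

  for (r in seq_len(config$n_records)) {
    rid <- sprintf("SYN-%05d", r)
    year <- sample(config$year_range[1]:config$year_range[2], 1)
    planted_eco <- eco_labels[stats::runif(length(eco_labels)) <
                                config$ecosystem_rates]

    # mentions: per class, maybe one member species (valid or synonym face)
    mention_rows <- list()
    surfaces <- character(0)
    for (cl in classes) {
      if (stats::runif(1) >= mention_rates[[cl]]) next
      i <- sp_by_class[[cl]][sample.int(length(sp_by_class[[cl]]), 1)]
      valid_id <- species$taxon_id[i]
      surf <- species$name[i]
      syns <- syn_by_accepted[[valid_id]]
      if (!is.null(syns) && stats::runif(1) < 0.5) {
        surf <- syns[sample.int(length(syns), 1)]
      }
      surfaces <- c(surfaces, surf)
      mention_rows[[length(mention_rows) + 1L]] <- data.frame(
        record_id = rid, taxon_id = valid_id, surface = surf,
        rank = "species", class = cl, ambiguous = FALSE,
        stringsAsFactors = FALSE)
    }
    if (length(hom_candidates) > 0 &&
        stats::runif(1) < config$homonym_mention_rate) {
      nm <- names(hom_candidates)[sample.int(length(hom_candidates), 1)]
      cand <- hom_candidates[[nm]]
      surfaces <- c(surfaces, nm)
      mention_rows[[length(mention_rows) + 1L]] <- data.frame(
        record_id = rid, taxon_id = cand$taxon_id, surface = nm,
        rank = "genus", class = cand$class, ambiguous = TRUE,
        stringsAsFactors = FALSE)
    }

    # field placement of ecosystem phrases
    phrase_field <- if (length(planted_eco) > 0) {
      stats::setNames(sample(c("title", "keywords", "abstract"),
                             length(planted_eco), replace = TRUE,
                             prob = c(0.3, 0.2, 0.5)), planted_eco)
    } else {
      character(0)
    }
    phrase_of <- stats::setNames(vapply(planted_eco, function(e)
      sample(queries[[e]], 1), ""), planted_eco)

    title_words <- filler(sample(5:8, 1))
    for (e in planted_eco[phrase_field[planted_eco] == "title"]) {
      at <- sample.int(length(title_words) + 1L, 1) - 1L
      title_words <- append(title_words, phrase_of[[e]], after = at)
    }
    title <- cap(paste(title_words, collapse = " "))

    keywords <- replicate(sample(2:4, 1),
                          paste(filler(sample(1:2, 1)), collapse = " "))
    for (e in planted_eco[phrase_field[planted_eco] == "keywords"]) {
      keywords <- c(keywords, phrase_of[[e]])
    }

    sents <- c(sentence(filler(sample(4:8, 1))),
               sentence(filler(sample(4:8, 1))))
    for (surf in surfaces) {
      sents <- c(sents, sentence(c(filler(sample(2:3, 1)), surf,
                                   filler(sample(2:3, 1)))))
    }
    for (e in planted_eco[phrase_field[planted_eco] == "abstract"]) {
      sents <- c(sents, sentence(c(filler(2), phrase_of[[e]], filler(2))))
    }
    sents <- c(sents, sentence(filler(sample(4:6, 1))))
    abstract <- cap(paste(sample(sents), collapse = " "))

    # database-generated keywords (ignored by the reader); occasionally
    # the only place an ecosystem phrase occurs
    id_field <- paste(filler(3), collapse = " ")
    if (length(planted_eco) == 0 && stats::runif(1) < config$kwplus_rate) {
      id_field <- paste(id_field,
                        sample(unlist(queries, use.names = FALSE), 1))
      kwplus_records <- c(kwplus_records, rid)
    }

    lines <- c(lines,
               "TY  - JOUR",
               paste0("AN  - ", rid),
               paste0("TI  - ", title),
               paste0("AB  - ", abstract),
               paste0("KW  - ", keywords),
               paste0("ID  - ", id_field),
               paste0("PY  - ", year),
               "ER  - ", "")

    if (length(planted_eco) > 0) {
      eco_log[[length(eco_log) + 1L]] <- data.frame(
        record_id = rid, ecosystem = planted_eco, stringsAsFactors = FALSE)
    }
    if (length(mention_rows) > 0) {
      men_log[[length(men_log) + 1L]] <- do.call(rbind, mention_rows)
    }
  }

  writeLines(lines, path, useBytes = TRUE)
  bind <- function(lst, proto) {
    if (length(lst) == 0) return(proto)
    out <- do.call(rbind, lst)
    rownames(out) <- NULL
    out
  }
  list(path = path,
       ecosystem_log = bind(eco_log,
                            data.frame(record_id = character(),
                                       ecosystem = character(),
                                       stringsAsFactors = FALSE)),
       mention_log = bind(men_log,
                          data.frame(record_id = character(),
                                     taxon_id = character(),
                                     surface = character(),
                                     rank = character(), class = character(),
                                     ambiguous = logical(),
                                     stringsAsFactors = FALSE)),
       mention_rates = mention_rates,
       kwplus_records = kwplus_records)
}

#' Simulate per-class effort data with known structure
#'
#' Generates classes whose log10 paper counts follow a known smooth of
#' log10 named richness plus phylum-level intercepts plus per-class
#' deviations -- the ground truth for the parameter-recovery check of
#' [fit_effort_richness()]. A few classes get large planted deviations
#' (the "over-" and "under-studied" extremes); the rest deviate only by
#' noise. Counts stay on the continuous scale so the planted deviations
#' are exact in log10 units.
#'
#' @param n_classes,n_phyla numbers of classes and phyla.
#' @param sd_phylum standard deviation of phylum intercepts (log10 papers).
#' @param sd_noise standard deviation of per-class noise (log10 papers).
#' @param n_over,n_under classes planted with `+effect` / `-effect`.
#' @param effect planted deviation magnitude in log10 units.
#' @param seed integer seed.
#' @return data frame with `class`, `phylum`, `n_species_worms`,
#'   `n_papers`, `true_deviation` (planted effect + noise) and
#'   `true_phylum_effect`.
#' @export
simulate_effort_classes <- function(n_classes = 60L, n_phyla = 6L,
                                    sd_phylum = 0.3, sd_noise = 0.1,
                                    n_over = 2L, n_under = 2L,
                                    effect = 1.2, seed = 1L) {
  stopifnot(n_classes >= n_phyla, n_over + n_under <= n_classes)
  set.seed(seed)
  x <- stats::runif(n_classes, 0.5, 4) # log10 named species, ~3 to 10000
  smooth <- 2 + 0.9 * x - 0.08 * x^2 # known concave effort curve
  phylum <- paste0("Phylum", rep_len(seq_len(n_phyla), n_classes))
  b <- stats::setNames(stats::rnorm(n_phyla, 0, sd_phylum),
                       paste0("Phylum", seq_len(n_phyla)))
  dev <- stats::rnorm(n_classes, 0, sd_noise)
  planted <- sample.int(n_classes, n_over + n_under)
  dev[planted[seq_len(n_over)]] <- dev[planted[seq_len(n_over)]] + effect
  if (n_under > 0) {
    under <- planted[n_over + seq_len(n_under)]
    dev[under] <- dev[under] - effect
  }
  y <- smooth + b[phylum] + dev
  data.frame(class = sprintf("Class%02d", seq_len(n_classes)),
             phylum = phylum,
             n_species_worms = 10^x,
             n_papers = 10^y,
             true_deviation = dev,
             true_phylum_effect = as.numeric(b[phylum]),
             planted = seq_len(n_classes) %in% planted,
             stringsAsFactors = FALSE)
}

#' Expected occurrence counts from a plant log
#'
#' Cross-tabulates the generator's ground truth into the taxon-by-
#' ecosystem counts the pipeline should reproduce: a (taxon, ecosystem)
#' cell counts distinct records planted in that ecosystem that carry a
#' mention of that taxon. With `include_ambiguous = FALSE` (matching the
#' default homonym-exclusion policy) ambiguous plants are left out.
#'
#' @param corpus result of [make_corpus()].
#' @param level `"class"` (class names) or `"species"` (taxon_ids;
#'   ambiguous genus plants never contribute species).
#' @param include_ambiguous include homonym plants (each candidate taxon
#'   credited), as under the `"all"` policy.
#' @param ecosystems optional full set of ecosystem columns (defaults to
#'   those with at least one planted record).
#' @return integer matrix, taxa x ecosystems.
#' @export
plant_crosstab <- function(corpus, level = c("class", "species"),
                           include_ambiguous = FALSE, ecosystems = NULL) {
  level <- match.arg(level)
  men <- corpus$mention_log
  if (level == "species") {
    men <- men[men$rank == "species", , drop = FALSE]
    men$taxon <- men$taxon_id
  } else {
    men$taxon <- men$class
  }
  if (!include_ambiguous) men <- men[!men$ambiguous, , drop = FALSE]
  eco <- corpus$ecosystem_log
  joined <- merge(unique(men[c("record_id", "taxon")]), eco,
                  by = "record_id")
  taxa <- sort(unique(joined$taxon))
  if (is.null(ecosystems)) ecosystems <- sort(unique(eco$ecosystem))
  out <- matrix(0L, length(taxa), length(ecosystems),
                dimnames = list(taxa, ecosystems))
  if (nrow(joined) > 0) {
    tab <- table(joined$taxon, joined$ecosystem)
    out[rownames(tab), colnames(tab)] <- as.integer(tab)
  }
  out
}
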