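# Bibliographic corpus handling: a minimal tagged-record (RIS/EndNote-export
# style) reader, the ecosystem phrase filter over title/author-keywords/
# abstract, and publication-year period binning.

#' Read bibliographic records from an RIS-style tagged file
#'
#' Parses tagged records (`TY`, `TI`, `AB`, `KW`, `PY`, `AN`, `ER`). `KW`
#' may repeat (author keywords); `ID` tags (database-generated
#' "KeyWords Plus"-style keywords) are deliberately ignored -- only author
#' keywords take part in downstream matching and filtering. Lines that do
#' not start a new tag are treated as continuations of the previous tag.
#'
#' @param path path to the tagged text file.
#' @param year_range admissible publication years (inclusive); the default
#'   is the 1957--2009 study window.
#' @return data frame with columns `record_id`, `title`, `abstract`,
#'   `year` (integer) and a list column `keywords`.
#' @details Entries lacking a parseable year, with a year outside
#'   `year_range`, or with both title and abstract empty are skipped; a
#'   single warning reports how many were dropped. `record_id` is taken
#'   from the `AN` tag when present, otherwise `REC<position>`.
#' @export
read_ris <- function(path, year_range = c(1957L, 2009L)) {
  if (!file.exists(path)) stop("RIS file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  tag_re <- "^([A-Z][A-Z0-9])  ?- ?(.*)$"
  is_tag <- grepl(tag_re, lines)

  entries <- list()
  cur <- list()
  cur_tag <- NULL
  flush <- function() {
    if (length(cur) > 0) entries[[length(entries) + 1L]] <<- cur
    cur <<- list()
    cur_tag <<- NULL
  }
  for (ln in seq_along(lines)) {
    line <- lines[ln]
    if (is_tag[ln]) {
      tag <- sub(tag_re, "\\1", line)
      val <- sub(tag_re, "\\2", line)
      if (tag == "ER") {
        flush()
      } else {
        cur[[length(cur) + 1L]] <- list(tag = tag, value = val)
        cur_tag <- length(cur)
      }
    } else if (!is.null(cur_tag) && nzchar(trimws(line))) {
      cur[[cur_tag]]$value <- paste(cur[[cur_tag]]$value, trimws(line))
    }
  }
  flush() # tolerate a final entry without ER

  n_skipped <- 0L
  recs <- vector("list", length(entries))
  for (i in seq_along(entries)) {
    tags <- vapply(entries[[i]], `[[`, "", "tag")
    vals <- vapply(entries[[i]], `[[`, "", "value")
    get1 <- function(t) {
      v <- vals[tags == t]
      if (length(v) == 0) "" else trimws(v[1])
    }
    title <- get1("TI")
    abstract <- get1("AB")
    keywords <- trimws(vals[tags == "KW"])
    keywords <- keywords[nzchar(keywords)]
    year_raw <- regmatches(get1("PY"), regexpr("[0-9]{4}", get1("PY")))
    year <- if (length(year_raw) == 1) as.integer(year_raw) else NA_integer_
    ok <- !is.na(year) && year >= year_range[1] && year <= year_range[2] &&
      (nzchar(title) || nzchar(abstract))
    if (!ok) {
      n_skipped <- n_skipped + 1L
      next
    }
    id <- get1("AN")
    if (!nzchar(id)) id <- sprintf("REC%04d", i)
    recs[[i]] <- data.frame(record_id = id, title = title,
                            abstract = abstract, year = year,
                            stringsAsFactors = FALSE)
    recs[[i]]$keywords <- list(keywords)
  }
  if (n_skipped > 0) {
    warning("skipped ", n_skipped,
            " malformed entr", if (n_skipped == 1) "y" else "ies",
            " (missing/out-of-range year or no title/abstract)")
  }
  recs <- recs[!vapply(recs, is.null, TRUE)]
  if (length(recs) == 0) {
    out <- data.frame(record_id = character(), title = character(),
                      abstract = character(), year = integer(),
                      stringsAsFactors = FALSE)
    out$keywords <- list()
    return(out)
  }
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

#' Read ecosystem phrase queries from a YAML file
#'
#' The file maps each ecosystem label to a list of exact multi-word
#' phrases, e.g. `coral_reef: ["coral reef", "coral reefs"]`.
#'
#' @param path YAML file path.
#' @return named list of character vectors.
#' @export
read_queries <- function(path) {
  q <- yaml::read_yaml(path)
  lapply(q, as.character)
}

#' Default ecosystem phrase queries
#'
#' The four-ecosystem query set used throughout: exact phrases with
#' singular/plural variants. Single words ("coral", "kelp", ...) are never
#' used on their own, so that hits are about the ecosystem rather than any
#' study of the organism.
#'
#' @return named list of character vectors keyed by ecosystem label.
#' @export
default_queries <- function() {
  list(
    coral_reef      = c("coral reef", "coral reefs"),
    kelp_forest     = c("kelp forest", "kelp forests"),
    mangrove_forest = c("mangrove forest", "mangrove forests"),
    seagrass_bed    = c("seagrass bed", "seagrass beds",
                        "seagrass meadow", "seagrass meadows")
  )
}

# Does any query phrase occur (as a whole, on word boundaries) in the
# searchable fields of one record? Tokenized sentence-wise, so a phrase
# cannot span sentence-final punctuation.
phrase_hit <- function(sent_tokens, phrase_tokens) {
  k <- length(phrase_tokens)
  for (toks in sent_tokens) {
    n <- length(toks)
    if (n < k) next
    for (s in seq_len(n - k + 1L)) {
      if (all(toks[s:(s + k - 1L)] == phrase_tokens)) return(TRUE)
    }
  }
  FALSE
}

record_sentences <- function(title, keywords, abstract) {
  c(tokenize_sentences(title),
    unlist(lapply(keywords, tokenize_sentences), recursive = FALSE),
    tokenize_sentences(abstract))
}

#' Assign records to ecosystems by exact phrase matching
#'
#' A record is assigned to every ecosystem one of whose phrases occurs
#' (case-insensitively, on word boundaries, as a whole phrase) in its
#' title, author keywords, or abstract. Records matching no query are
#' dropped; one record may belong to several ecosystems.
#'
#' @param records data frame from [read_ris()].
#' @param queries named list of phrase vectors (see [default_queries()]);
#'   every phrase must have at least two words.
#' @return named list: ecosystem label -> character vector of record_ids.
#' @export
filter_corpus <- function(records, queries = default_queries()) {
  for (lab in names(queries)) {
    nw <- lengths(strsplit(queries[[lab]], "[[:space:]]+"))
    if (any(nw < 2)) {
      stop("ecosystem query phrases must have >= 2 words; offending ",
           "phrase(s) under '", lab, "': ",
           paste(queries[[lab]][nw < 2], collapse = ", "))
    }
  }
  phrase_tok <- lapply(queries, function(ph)
    lapply(ph, function(p) tokenize_sentences(p)[[1]]))
  out <- stats::setNames(vector("list", length(queries)), names(queries))
  for (lab in names(queries)) out[[lab]] <- character(0)
  for (i in seq_len(nrow(records))) {
    sents <- record_sentences(records$title[i], records$keywords[[i]],
                              records$abstract[i])
    if (length(sents) == 0) next
    for (lab in names(queries)) {
      hit <- any(vapply(phrase_tok[[lab]], function(pt)
        phrase_hit(sents, pt), logical(1)))
      if (hit) out[[lab]] <- c(out[[lab]], records$record_id[i])
    }
  }
  out
}

#' Partition records into publication-year periods
#'
#' Default boundaries reproduce the three study periods: before 2000,
#' 2000--2006, and 2007--2009 (2006 belongs to the middle period).
#'
#' @param records data frame with a `year` column.
#' @param boundaries strictly increasing integer upper bounds (inclusive)
#'   of each period; the first period is open below.
#' @return named list of record data frames, one per period; every record
#'   falls in exactly one.
#' @export
split_periods <- function(records, boundaries = c(1999L, 2006L, 2009L)) {
  if (is.unsorted(boundaries, strictly = TRUE)) {
    stop("period boundaries must be strictly increasing")
  }
  over <- records$year > boundaries[length(boundaries)]
  if (any(over)) {
    stop("configuration error: record(s) outside all periods: ",
         paste(records$record_id[over], collapse = ", "))
  }
  labels <- c(paste0("pre-", boundaries[1] + 1L),
              if (length(boundaries) > 1)
                paste0(boundaries[-length(boundaries)] + 1L, "-",
                       boundaries[-1]))
  bin <- findInterval(records$year, boundaries + 1L) + 1L
  out <- lapply(seq_along(labels), function(b)
    records[bin == b, , drop = FALSE])
  stats::setNames(out, labels)
}
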