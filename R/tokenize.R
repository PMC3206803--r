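# Shared text normalization used by the ecosystem filter and the n-gram
# extractor, so that phrase matching and name matching see identical tokens.

#' Normalize a scientific name or token for index lookup
#'
#' Lowercases, strips surrounding (non-alphanumeric) punctuation from each
#' word, and collapses internal whitespace. Titles capitalize words and
#' registry names are mixed-case, so all index lookups go through this.
#'
#' @param x character vector of names or tokens.
#' @return character vector of normalized strings.
#' @export
#' @examples
#' normalize_name(c("  Acropora   Millepora.", "CORAL"))
normalize_name <- function(x) {
  x <- tolower(x)
  x <- gsub("-", " ", x, fixed = TRUE)
  x <- gsub("[[:space:]]+", " ", x)
  # strip leading/trailing punctuation around each word
  x <- gsub("(^|(?<= ))[^[:alnum:] ]+", "", x, perl = TRUE)
  x <- gsub("[^[:alnum:] ]+((?= )|$)", "", x, perl = TRUE)
  x <- gsub("[[:space:]]+", " ", x)
  trimws(x)
}

# Split free text into sentences (on . ! ?), then each sentence into
# normalized tokens. Hyphens split tokens ("coral-reef" -> "coral", "reef");
# punctuation at token edges is stripped. Returns a list of character
# vectors, one per sentence; empty sentences are dropped.
tokenize_sentences <- function(text) {
  if (length(text) == 0 || is.na(text) || !nzchar(text)) return(list())
  sentences <- strsplit(text, "[.!?]+")[[1]]
  out <- lapply(sentences, function(s) {
    s <- tolower(s)
    s <- gsub("-", " ", s, fixed = TRUE)
    toks <- strsplit(s, "[[:space:]]+")[[1]]
    toks <- gsub("^[^[:alnum:]]+|[^[:alnum:]]+$", "", toks)
    toks[nzchar(toks)]
  })
  out[vapply(out, length, 1L) > 0L]
}
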