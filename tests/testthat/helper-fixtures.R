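# Shared fixtures built in code, plus brute-force oracles kept deliberately
# independent of the implementation paths they check.

RANKS7 <- c("kingdom", "phylum", "class", "order", "family", "genus",
            "species")

# one registry row as a data.frame, lineage given as named vector
reg_row <- function(id, name, rank, status, acc, lin) {
  full <- setNames(rep("", 7), RANKS7)
  full[names(lin)] <- lin
  out <- data.frame(taxon_id = id, name = name, rank = rank,
                    status = status, accepted_id = acc, t(full),
                    stringsAsFactors = FALSE)
  out
}

# tiny two-kingdom registry: 2 genera of animals (one with 2 congeneric
# species), 1 plant genus, a synonym, and an optional cross-kingdom
# homonymous genus name
tiny_registry_df <- function(homonym = FALSE) {
  lin_a <- c(kingdom = "Animalia", phylum = "Molluscoida", class = "Gastrozoa",
             order = "Gastralia", family = "Gastridae")
  lin_b <- c(kingdom = "Plantae", phylum = "Chlorophytina",
             class = "Ulvopsida", order = "Ulvales", family = "Ulvaceae")
  hom_name <- if (homonym) "Velara" else "Planta"
  rows <- list(
    reg_row("K1", "Animalia", "kingdom", "valid", "K1",
            c(kingdom = "Animalia")),
    reg_row("K2", "Plantae", "kingdom", "valid", "K2",
            c(kingdom = "Plantae")),
    reg_row("P1", "Molluscoida", "phylum", "valid", "P1", lin_a[1:2]),
    reg_row("P2", "Chlorophytina", "phylum", "valid", "P2", lin_b[1:2]),
    reg_row("C1", "Gastrozoa", "class", "valid", "C1", lin_a[1:3]),
    reg_row("C2", "Ulvopsida", "class", "valid", "C2", lin_b[1:3]),
    reg_row("O1", "Gastralia", "order", "valid", "O1", lin_a[1:4]),
    reg_row("O2", "Ulvales", "order", "valid", "O2", lin_b[1:4]),
    reg_row("F1", "Gastridae", "family", "valid", "F1", lin_a),
    reg_row("F2", "Ulvaceae", "family", "valid", "F2", lin_b),
    reg_row("G1", "Velara", "genus", "valid", "G1", c(lin_a, genus = "Velara")),
    reg_row("G2", hom_name, "genus", "valid", "G2",
            c(lin_b, genus = hom_name)),
    reg_row("S1", "Velara prima", "species", "valid", "S1",
            c(lin_a, genus = "Velara", species = "Velara prima")),
    reg_row("S2", "Velara secunda", "species", "valid", "S2",
            c(lin_a, genus = "Velara", species = "Velara secunda")),
    reg_row("S3", paste(hom_name, "viridis"), "species", "valid", "S3",
            c(lin_b, genus = hom_name,
              species = paste(hom_name, "viridis"))),
    reg_row("Y1", "Antiqua prima", "species", "synonym", "S1",
            c(lin_a, genus = "Velara", species = "Antiqua prima"))
  )
  do.call(rbind, rows)
}

tiny_registry <- function(homonym = FALSE) {
  registry_from_df(tiny_registry_df(homonym),
                   kingdoms = c("Animalia", "Plantae"))
}

fixture_path <- function(file) {
  system.file("extdata", file, package = "taxolit", mustWork = TRUE)
}

fixture_registry <- function() {
  read_registry(fixture_path("registry_synthetic_40.tsv"),
                kingdoms = c("Animalia", "Plantae"))
}

# records data frame from plain fields (keywords as character vector)
bib_records <- function(...) {
  entries <- list(...)
  out <- do.call(rbind, lapply(entries, function(e) {
    d <- data.frame(record_id = e$record_id,
                    title = if (is.null(e$title)) "" else e$title,
                    abstract = if (is.null(e$abstract)) "" else e$abstract,
                    year = if (is.null(e$year)) 2000L else e$year,
                    stringsAsFactors = FALSE)
    d$keywords <- list(if (is.null(e$keywords)) character(0) else e$keywords)
    d
  }))
  rownames(out) <- NULL
  out
}

# ---- brute-force oracles -------------------------------------------------

# n-grams by naive double loop over raw whitespace tokens of each sentence
bf_ngrams <- function(texts) {
  grams <- character(0)
  for (txt in texts) {
    if (is.na(txt) || !nzchar(txt)) next
    for (s in strsplit(txt, "[.!?]+")[[1]]) {
      toks <- strsplit(tolower(gsub("-", " ", s)), "[[:space:]]+")[[1]]
      toks <- gsub("^[^[:alnum:]]+|[^[:alnum:]]+$", "", toks)
      toks <- toks[nzchar(toks)]
      n <- length(toks)
      if (n == 0) next
      for (i in seq_len(n)) {
        grams <- c(grams, toks[i])
        if (i < n) grams <- c(grams, paste(toks[i], toks[i + 1]))
      }
    }
  }
  unique(grams)
}

# delta+ by an exhaustive pair loop directly over lineage columns
bf_delta_plus <- function(registry, ids) {
  ids <- unique(ids)
  rec <- registry$records[match(ids, registry$records$taxon_id), ]
  n <- length(ids)
  tot <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      la <- unlist(rec[i, RANKS7], use.names = FALSE)
      lb <- unlist(rec[j, RANKS7], use.names = FALSE)
      depth <- 0
      for (k in 1:7) {
        if (la[k] == lb[k] && nzchar(la[k])) depth <- k else break
      }
      steps <- 2 * (7 - max(depth, 1))
      tot <- tot + steps / 12 * 100
    }
  }
  tot / (n * (n - 1) / 2)
}

# straight-line transcription of the classic Chao1 formulas
bf_chao1 <- function(x) {
  x <- x[x > 0]
  S <- length(x)
  f1 <- sum(x == 1)
  f2 <- sum(x == 2)
  if (f2 > 0) {
    est <- S + f1 * f1 / (2 * f2)
    G <- f1 / f2
    v <- f2 * (G^2 / 2 + G^3 + G^4 / 4)
  } else {
    est <- S + f1 * (f1 - 1) / 2
    v <- if (f1 > 0) {
      f1 * (f1 - 1) / 2 + f1 * (2 * f1 - 1)^2 / 4 - f1^4 / (4 * est)
    } else 0
  }
  c(est = est, se = sqrt(max(v, 0)))
}

# hypergeometric rarefaction by direct choose() arithmetic (small counts)
bf_rarefy <- function(x, n) {
  x <- x[x > 0]
  N <- sum(x)
  q <- choose(N - x, n) / choose(N, n)
  e <- sum(1 - q)
  v <- sum(q * (1 - q))
  S <- length(x)
  if (S >= 2) {
    for (i in 1:(S - 1)) {
      for (j in (i + 1):S) {
        qq <- choose(N - x[i] - x[j], n) / choose(N, n)
        v <- v + 2 * (qq - q[i] * q[j])
      }
    }
  }
  c(e = e, v = max(v, 0))
}

# align two count matrices on the union of row names (zero filled)
align_counts <- function(a, b, cols) {
  taxa <- sort(union(rownames(a), rownames(b)))
  out_a <- out_b <- matrix(0L, length(taxa), length(cols),
                           dimnames = list(taxa, cols))
  out_a[rownames(a), intersect(colnames(a), cols)] <-
    a[, intersect(colnames(a), cols)]
  out_b[rownames(b), intersect(colnames(b), cols)] <-
    b[, intersect(colnames(b), cols)]
  list(a = out_a, b = out_b)
}
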