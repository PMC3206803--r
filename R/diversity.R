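# Diversity battery over paper-count "abundances": Shannon evenness, Chao1
# richness with standard error, average taxonomic distinctness (delta+)
# with a randomization funnel, and individual-based rarefaction with
# analytic confidence bounds.

#' Shannon evenness of an abundance vector
#'
#' `-sum(Pi * ln(Pi)) / ln(S)`, where `Pi` is the proportion of total
#' abundance in taxon i and `S` the number of taxa with positive
#' abundance. Equals 1 for a perfectly even community. Natural logs
#' throughout.
#'
#' @param x numeric vector of non-negative abundances (paper counts);
#'   zeros are dropped.
#' @return evenness in `[0, 1]`.
#' @export
shannon_evenness <- function(x) {
  x <- x[!is.na(x)]
  if (any(x < 0)) stop("abundances must be non-negative")
  x <- x[x > 0]
  s <- length(x)
  if (s < 2) {
    stop("evenness is undefined for fewer than 2 taxa (ln S = 0)")
  }
  p <- x / sum(x)
  h <- -sum(p * log(p))
  h / log(s)
}

#' Chao1 richness estimate with standard error
#'
#' Classic abundance-based Chao1: `S_obs + f1^2 / (2 f2)` when doubletons
#' are present, with the bias-corrected fallback
#' `S_obs + f1 (f1 - 1) / 2` when `f2 = 0`. The standard error comes from
#' the matching classic variance formulas (Chao 1987).
#'
#' @param x numeric vector of non-negative integer abundances.
#' @return list with `estimate`, `se`, `S_obs`, `f1`, `f2`, and `variant`
#'   (`"classic"` or `"bias-corrected-f2=0"`).
#' @export
chao1 <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) stop("empty abundance vector")
  if (any(x < 0)) stop("abundances must be non-negative")
  x <- x[x > 0]
  if (length(x) == 0) stop("no taxa with positive abundance")
  s_obs <- length(x)
  f1 <- sum(x == 1)
  f2 <- sum(x == 2)
  if (f2 > 0) {
    est <- s_obs + f1^2 / (2 * f2)
    g <- f1 / f2
    v <- f2 * (g^2 / 2 + g^3 + g^4 / 4)
    variant <- "classic"
  } else {
    est <- s_obs + f1 * (f1 - 1) / 2
    v <- if (f1 > 0) {
      f1 * (f1 - 1) / 2 + f1 * (2 * f1 - 1)^2 / 4 - f1^4 / (4 * est)
    } else {
      0
    }
    variant <- "bias-corrected-f2=0"
  }
  list(estimate = est, se = sqrt(max(v, 0)), S_obs = s_obs,
       f1 = f1, f2 = f2, variant = variant)
}

#' Average taxonomic distinctness (delta+) of a species set
#'
#' The mean taxonomic path length over all unordered pairs of species,
#' with equal step weights across the 7-rank ladder and rescaled so the
#' maximum possible path (species sharing only their kingdom) equals 100.
#' Presence/absence only: abundances and duplicate ids are ignored. Low
#' values mean the set is concentrated in few taxonomic groups.
#'
#' @param species_ids taxon_ids of valid species (>= 2 distinct).
#' @param registry a `taxonomy_registry`.
#' @param period_label optional label carried through to the result.
#' @return list with `delta_plus` (in `[0, 100]`), `S`, `period_label`.
#' @export
delta_plus <- function(species_ids, registry, period_label = NULL) {
  species_ids <- unique(species_ids)
  if (length(species_ids) < 2) {
    stop("delta+ is undefined for fewer than 2 species")
  }
  d <- taxon_distance_matrix(registry, species_ids)
  list(delta_plus = mean(d[upper.tri(d)]),
       S = length(species_ids),
       period_label = period_label)
}

#' Randomization funnel for taxonomic distinctness
#'
#' For each subset size m, draws `n_sim` random subsets (without
#' replacement) from a master species pool and reports the simulated mean
#' of delta+ and approximate 2-standard-deviation limits -- the null
#' envelope against which observed ecosystem/period points are judged:
#' points below the funnel represent significantly narrower taxonomic
#' breadth than a random draw of the same size.
#'
#' @param pool_ids master pool of valid species taxon_ids (conventionally
#'   the union of species observed across all ecosystems and periods
#'   under comparison).
#' @param sizes integer subset sizes, each in `[2, length(pool_ids)]`.
#' @param registry a `taxonomy_registry`.
#' @param n_sim number of random subsets per size (>= 2).
#' @param seed optional integer; when given, `set.seed(seed)` is called so
#'   the envelope is reproducible bit-for-bit.
#' @return data frame with columns `size`, `mean`, `sd`, `lower`, `upper`
#'   (mean -/+ 2 sd); attributes `n_sim` and `seed`.
#' @export
distinctness_funnel <- function(pool_ids, sizes, registry,
                                n_sim = 1000L, seed = NULL) {
  pool_ids <- unique(pool_ids)
  n <- length(pool_ids)
  sizes <- as.integer(sizes)
  if (any(sizes < 2)) stop("funnel subset sizes must be >= 2")
  if (any(sizes > n)) stop("funnel subset size exceeds pool size (", n, ")")
  if (n_sim < 2) stop("n_sim must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  d <- taxon_distance_matrix(registry, pool_ids)
  sim_one <- function(m) {
    vals <- vapply(seq_len(n_sim), function(k) {
      idx <- sample.int(n, m)
      sub <- d[idx, idx]
      mean(sub[upper.tri(sub)])
    }, numeric(1))
    c(mean = mean(vals), sd = stats::sd(vals))
  }
  stats_m <- vapply(sizes, sim_one, numeric(2))
  out <- data.frame(size = sizes,
                    mean = stats_m["mean", ],
                    sd = stats_m["sd", ])
  out$lower <- out$mean - 2 * out$sd
  out$upper <- out$mean + 2 * out$sd
  attr(out, "n_sim") <- as.integer(n_sim)
  attr(out, "seed") <- seed
  out
}

#' Individual-based rarefaction with analytic confidence bounds
#'
#' Expected species richness in a random subsample of n individuals
#' (papers) drawn without replacement:
#' `E[S_n] = sum_i (1 - choose(N - N_i, n) / choose(N, n))`, with the
#' standard hypergeometric variance (Heck et al. 1975) and a normal
#' 95% interval truncated below at 1 (any subsample of one individual
#' contains one species).
#'
#' @param x numeric vector of positive integer abundances (paper counts).
#' @param sizes subsample sizes, each in `[1, sum(x)]`.
#' @return data frame with `size`, `expected_S`, `sd`, `ci_low`,
#'   `ci_high`.
#' @export
rarefy_curve <- function(x, sizes) {
  x <- x[!is.na(x)]
  if (any(x < 0)) stop("abundances must be non-negative")
  x <- x[x > 0]
  if (length(x) == 0) stop("empty abundance vector")
  N <- sum(x)
  sizes <- as.integer(sizes)
  if (any(sizes < 1)) stop("subsample sizes must be >= 1")
  if (any(sizes > N)) {
    stop("subsample size exceeds total abundance (", N, ")")
  }
  one <- function(n) {
    # q_i = P(species i absent from the subsample)
    lq <- lchoose(N - x, n) - lchoose(N, n)
    q <- ifelse(N - x < n, 0, exp(lq))
    e <- sum(1 - q)
    # Heck et al. variance: singles + pairwise joint-absence terms
    v <- sum(q * (1 - q))
    if (length(x) >= 2) {
      ij <- utils::combn(length(x), 2)
      xi <- x[ij[1, ]]
      xj <- x[ij[2, ]]
      lqq <- lchoose(N - xi - xj, n) - lchoose(N, n)
      qq <- ifelse(N - xi - xj < n, 0, exp(lqq))
      v <- v + 2 * sum(qq - q[ij[1, ]] * q[ij[2, ]])
    }
    c(e = e, v = max(v, 0))
  }
  res <- vapply(sizes, one, numeric(2))
  sdv <- sqrt(res["v", ])
  data.frame(size = sizes,
             expected_S = res["e", ],
             sd = sdv,
             ci_low = pmax(res["e", ] - 1.96 * sdv, 1),
             ci_high = res["e", ] + 1.96 * sdv)
}
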