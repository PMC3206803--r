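# Research-effort models per taxonomic class: binomial occurrence
# probability in the literature, a log10-log10 effort-versus-known-richness
# spline fit with phylum-level random intercepts, and residual-based
# over-/under-study rankings.

#' Probability of occurrence in the literature
#'
#' Intercept-only binomial model per class and ecosystem: the point
#' estimate is the observed proportion `n_hits / n_total` (the binomial
#' MLE) with a 95% Wald interval on the log-odds scale, back-transformed.
#' Degenerate counts (0 or all papers) get a one-sided interval via a 0.5
#' continuity adjustment and are flagged.
#'
#' @param n_hits papers mentioning the class (vectorized).
#' @param n_total total assigned papers in the ecosystem.
#' @param conf confidence level.
#' @return data frame with `probability`, `ci_low`, `ci_high`,
#'   `degenerate`.
#' @export
occurrence_probability <- function(n_hits, n_total, conf = 0.95) {
  if (any(n_total < 1)) stop("n_total must be >= 1")
  if (any(n_hits < 0) || any(n_hits > n_total)) {
    stop("n_hits must lie in [0, n_total]")
  }
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- n_hits / n_total
  degenerate <- n_hits == 0 | n_hits == n_total
  # regular Wald interval on the logit scale
  se <- ifelse(degenerate, NA_real_, sqrt(1 / n_hits + 1 / (n_total - n_hits)))
  lo <- stats::plogis(stats::qlogis(p) - z * se)
  hi <- stats::plogis(stats::qlogis(p) + z * se)
  # continuity-adjusted one-sided bounds for the degenerate cases
  h_adj <- n_hits + 0.5
  m_adj <- n_total - n_hits + 0.5
  se_adj <- sqrt(1 / h_adj + 1 / m_adj)
  p_adj <- h_adj / (n_total + 1)
  lo[degenerate & n_hits == 0] <- 0
  hi[degenerate & n_hits == 0] <-
    stats::plogis(stats::qlogis(p_adj) + z * se_adj)[degenerate & n_hits == 0]
  hi[degenerate & n_hits == n_total] <- 1
  lo[degenerate & n_hits == n_total] <-
    stats::plogis(stats::qlogis(p_adj) - z * se_adj)[degenerate &
                                                       n_hits == n_total]
  data.frame(probability = p, ci_low = lo, ci_high = hi,
             degenerate = degenerate)
}

#' Fit the effort-versus-richness model
#'
#' Models `log10(papers per class)` as a smooth function of
#' `log10(globally named species per class)` -- a natural cubic spline of
#' fixed degrees of freedom -- plus a phylum-level random intercept, so
#' that taxonomic non-independence among classes of one phylum does not
#' masquerade as over- or under-study. Both log10 transforms remove the
#' "trumpeting" of variances seen on raw counts.
#'
#' The random intercept is estimated by iterative shrinkage: fit the
#' smooth on intercept-adjusted responses, take phylum means of the
#' residuals, shrink them toward zero by the variance-ratio factor
#' `sigma_b^2 / (sigma_b^2 + sigma_e^2 / n_phylum)` (moment estimates),
#' and refit until the intercepts change by less than `tol`.
#'
#' Classes with zero papers are excluded from the regression (log of zero)
#' but are reported in `excluded` and surface as "unstudied" in
#' [rank_classes()].
#'
#' @param rows data frame with columns `class`, `phylum`, `n_papers`,
#'   `n_species_worms` (globally named valid species in the class).
#' @param spline_df degrees of freedom of the natural spline (default 3).
#' @param max_iter,tol iteration control for the shrinkage loop.
#' @return an `effort_fit`: list with `table` (class, phylum, counts,
#'   `log_papers`, `log_species`, `fitted`, `residual`), `phylum_effects`,
#'   `sigma_b2`, `sigma_e2`, `r_squared`, `excluded`, `converged`,
#'   `iterations`.
#' @export
fit_effort_richness <- function(rows, spline_df = 3L, max_iter = 200L,
                                tol = 1e-8) {
  stopifnot(all(c("class", "phylum", "n_papers", "n_species_worms") %in%
                  names(rows)))
  excluded <- rows[rows$n_papers < 1, , drop = FALSE]
  rows <- rows[rows$n_papers >= 1, , drop = FALSE]
  if (nrow(rows) < 8) {
    stop("need >= 8 classes with at least one paper to fit the model")
  }
  if (any(rows$n_species_worms < 1)) {
    stop("n_species_worms must be >= 1 for fitted classes")
  }
  y <- log10(rows$n_papers)
  x <- log10(rows$n_species_worms)
  if (length(unique(x)) == 1) {
    stop("degenerate predictor: all classes have equal known richness")
  }
  phylum <- as.character(rows$phylum)
  phyla <- sort(unique(phylum))
  use_ranef <- length(phyla) >= 3
  if (!use_ranef) {
    warning("fewer than 3 phyla: fitting without a phylum random effect")
  }

  basis <- splines::ns(x, df = spline_df)
  b <- stats::setNames(rep(0, length(phyla)), phyla)
  n_p <- as.numeric(table(phylum)[phyla])
  sigma_b2 <- sigma_e2 <- 0
  iter <- 0L
  converged <- TRUE
  repeat {
    iter <- iter + 1L
    fit <- stats::lm.fit(cbind(1, basis), y - b[phylum])
    smooth <- drop(cbind(1, basis) %*% fit$coefficients)
    if (!use_ranef) break
    r <- y - smooth
    m_p <- stats::setNames(as.numeric(tapply(r, phylum, mean)[phyla]),
                           phyla)
    within <- r - m_p[phylum]
    dfree <- max(length(y) - length(phyla), 1L)
    sigma_e2 <- sum(within^2) / dfree
    sigma_b2 <- max(mean(m_p^2 - sigma_e2 / n_p), 0)
    denom <- sigma_b2 + sigma_e2 / n_p
    shrink <- ifelse(denom > 0, sigma_b2 / denom, 0)
    b_new <- m_p * shrink
    delta <- max(abs(b_new - b))
    b <- b_new
    if (delta < tol) break
    if (iter >= max_iter) {
      converged <- FALSE
      warning("shrinkage loop did not converge in ", max_iter,
              " iterations (last change ", format(delta), ")")
      break
    }
  }
  fitted_full <- smooth + if (use_ranef) b[phylum] else 0
  residual <- y - fitted_full
  r2 <- 1 - sum(residual^2) / sum((y - mean(y))^2)
  tab <- data.frame(class = rows$class, phylum = phylum,
                    n_papers = rows$n_papers,
                    n_species_worms = rows$n_species_worms,
                    log_papers = y, log_species = x,
                    fitted = as.numeric(fitted_full),
                    residual = as.numeric(residual),
                    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  structure(list(table = tab,
                 phylum_effects = if (use_ranef) b else NULL,
                 sigma_b2 = sigma_b2, sigma_e2 = sigma_e2,
                 r_squared = r2,
                 spline_df = spline_df,
                 excluded = excluded,
                 converged = converged,
                 iterations = iter),
            class = "effort_fit")
}

#' @export
print.effort_fit <- function(x, ...) {
  cat("Effort vs richness fit:", nrow(x$table), "classes,",
      if (is.null(x$phylum_effects)) "no phylum random effect"
      else paste(length(x$phylum_effects), "phylum random intercepts"),
      "\n  R-squared:", round(x$r_squared, 3),
      " sigma_b^2:", signif(x$sigma_b2, 3),
      " sigma_e^2:", signif(x$sigma_e2, 3), "\n")
  invisible(x)
}

# deterministic ordering: value descending, ties broken by class name
order_by_value <- function(class, value) order(-value, class)

#' Rank classes by effort residual
#'
#' The k most over-studied (largest positive residual: more papers than
#' their global named richness predicts) and k most under-studied classes.
#' Classes excluded from the regression for having zero papers are
#' reported separately as `unstudied`. Ties break lexicographically by
#' class name, so rankings are deterministic.
#'
#' @param fit an `effort_fit`.
#' @param k list length (default 10).
#' @return list with `top`, `bottom` (data frames sorted outward from the
#'   extremes) and `unstudied` (character vector of class names).
#' @export
rank_classes <- function(fit, k = 10L) {
  stopifnot(inherits(fit, "effort_fit"))
  tab <- fit$table
  if (k > nrow(tab)) {
    warning("k = ", k, " exceeds the ", nrow(tab),
            " fitted classes; truncating")
    k <- nrow(tab)
  }
  o <- order_by_value(tab$class, tab$residual)
  top <- tab[o[seq_len(k)], , drop = FALSE]
  bottom <- tab[rev(o)[seq_len(k)], , drop = FALSE]
  rownames(top) <- rownames(bottom) <- NULL
  unstudied <- sort(as.character(fit$excluded$class))
  list(top = top, bottom = bottom, unstudied = unstudied)
}

#' Rank classes by occurrence probability, per ecosystem
#'
#' @param prob_table data frame with columns `class`, `ecosystem`,
#'   `probability` (e.g. assembled from [occurrence_probability()]).
#' @param k list length per ecosystem.
#' @return named list (by ecosystem) of data frames sorted by descending
#'   probability, ties broken by class name.
#' @export
rank_by_probability <- function(prob_table, k = 10L) {
  stopifnot(all(c("class", "ecosystem", "probability") %in%
                  names(prob_table)))
  out <- lapply(split(prob_table, prob_table$ecosystem), function(d) {
    kk <- k
    if (kk > nrow(d)) {
      warning("k = ", k, " exceeds the ", nrow(d), " classes in ",
              d$ecosystem[1], "; truncating")
      kk <- nrow(d)
    }
    o <- order_by_value(d$class, d$probability)
    res <- d[o[seq_len(kk)], , drop = FALSE]
    rownames(res) <- NULL
    res
  })
  out
}
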