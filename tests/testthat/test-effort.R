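test_that("occurrence probability is the binomial MLE with a Wald CI", {
  got <- occurrence_probability(50, 100)
  expect_equal(got$probability, 0.5)
  expect_false(got$degenerate)
  # symmetric on the logit scale around 0.5
  expect_equal(got$ci_low, 1 - got$ci_high)

  # independently coded logit-scale Wald interval, 7 of 322
  g <- occurrence_probability(7, 322)
  p <- 7 / 322
  se <- sqrt(1 / 7 + 1 / 315)
  expect_equal(g$probability, p)
  expect_equal(g$ci_low, plogis(log(p / (1 - p)) - qnorm(0.975) * se))
  expect_equal(g$ci_high, plogis(log(p / (1 - p)) + qnorm(0.975) * se))

  # degenerate counts: one-sided interval, flagged
  z <- occurrence_probability(0, 100)
  expect_equal(z$probability, 0)
  expect_equal(z$ci_low, 0)
  expect_true(z$degenerate && z$ci_high > 0)
  o <- occurrence_probability(100, 100)
  expect_equal(o$ci_high, 1)
  expect_true(o$ci_low < 1)
  expect_error(occurrence_probability(5, 4), "n_hits")
})

test_that("the point estimate equals n_hits/n_total exactly (vectorized)", {
  set.seed(12)
  n <- sample(10:500, 50, replace = TRUE)
  h <- vapply(n, function(k) sample(0:k, 1), 1L)
  got <- occurrence_probability(h, n)
  expect_equal(got$probability, h / n)
  expect_true(all(got$ci_low <= got$probability + 1e-12))
  expect_true(all(got$ci_high >= got$probability - 1e-12))
})

test_that("noiseless single-phylum data are interpolated exactly", {
  x <- seq(1, 4, length.out = 12)
  rows <- data.frame(class = sprintf("c%02d", 1:12), phylum = "P1",
                     n_species_worms = 10^x, n_papers = 10^(0.5 + 0.6 * x))
  fit <- suppressWarnings(fit_effort_richness(rows))
  expect_equal(fit$table$residual, rep(0, 12), tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
})

test_that("within-phylum residuals vanish on noiseless grouped data", {
  set.seed(2)
  x <- runif(30, 1, 4)
  phylum <- rep(paste0("P", 1:5), each = 6)
  b <- c(P1 = 0.4, P2 = -0.3, P3 = 0.1, P4 = -0.2, P5 = 0)
  rows <- data.frame(class = sprintf("c%02d", 1:30), phylum = phylum,
                     n_species_worms = 10^x,
                     n_papers = 10^(1 + 0.5 * x + b[phylum]))
  fit <- fit_effort_richness(rows)
  sums <- tapply(fit$table$residual, fit$table$phylum, sum)
  expect_true(all(abs(sums) < 1e-6))
  expect_equal(sort(names(sort(fit$phylum_effects))),
               sort(names(b)))
  expect_equal(unname(fit$phylum_effects[names(b)]) -
                 mean(fit$phylum_effects), unname(b) - mean(b),
               tolerance = 1e-4)
})

test_that("refitting identical input gives identical residuals", {
  sim <- simulate_effort_classes(seed = 5)
  f1 <- fit_effort_richness(sim)
  f2 <- fit_effort_richness(sim)
  expect_identical(f1$table$residual, f2$table$residual)
})

test_that("doubling papers shifts the response, not the ranking", {
  sim <- simulate_effort_classes(seed = 9)
  f1 <- fit_effort_richness(sim)
  sim2 <- sim
  sim2$n_papers <- sim2$n_papers * 2
  f2 <- fit_effort_richness(sim2)
  expect_equal(f2$table$log_papers - f1$table$log_papers,
               rep(log10(2), nrow(sim)))
  expect_equal(order(-f1$table$residual, f1$table$class),
               order(-f2$table$residual, f2$table$class))
})

test_that("planted extreme classes are recovered at the ranking extremes", {
  sim <- simulate_effort_classes(n_classes = 60, n_phyla = 6,
                                 sd_phylum = 0.3, sd_noise = 0.1,
                                 n_over = 2, n_under = 2, seed = 14)
  fit <- fit_effort_richness(sim)
  expect_gt(cor(fit$table$residual,
                sim$true_deviation[match(fit$table$class, sim$class)]), 0.9)
  rk <- rank_classes(fit, k = 2)
  over <- sim$class[sim$planted & sim$true_deviation > 0]
  under <- sim$class[sim$planted & sim$true_deviation < 0]
  expect_setequal(rk$top$class, over)
  expect_setequal(rk$bottom$class, under)
})

test_that("model guards: few classes, degenerate predictor, few phyla", {
  base <- data.frame(class = paste0("c", 1:10), phylum = "P1",
                     n_species_worms = 10^runif(10, 1, 3),
                     n_papers = 10 + 1:10)
  expect_error(fit_effort_richness(base[1:5, ]), ">= 8")
  flat <- base
  flat$n_species_worms <- 100
  expect_error(suppressWarnings(fit_effort_richness(flat)), "degenerate")
  expect_warning(fit_effort_richness(base), "fewer than 3 phyla")
})

test_that("rankings sort deterministically and report unstudied classes", {
  rows <- data.frame(
    class = c("Beta", "Alpha", "Gamma", paste0("c", 1:7), "Omitted"),
    phylum = rep(c("P1", "P2", "P3"), length.out = 11),
    n_species_worms = 10^seq(1, 3, length.out = 11),
    n_papers = c(rep(5, 10), 0))
  fit <- fit_effort_richness(rows)
  rk <- rank_classes(fit, k = 3)
  expect_equal(rk$unstudied, "Omitted")
  expect_equal(nrow(rk$top), 3)
  # tie on residual -> lexicographic class order, stable across runs
  tied <- fit$table[order(-fit$table$residual, fit$table$class), ]
  expect_identical(rk$top$class, tied$class[1:3])
  expect_warning(rank_classes(fit, k = 99), "truncating")

  prob <- data.frame(class = c("B", "A", "C"), ecosystem = "coral_reef",
                     probability = c(0.2, 0.2, 0.9))
  rp <- rank_by_probability(prob, k = 3)
  expect_equal(rp$coral_reef$class, c("C", "A", "B"))
})
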