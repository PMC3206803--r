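test_that("evenness is 1 for uniform counts and matches the formula", {
  expect_equal(shannon_evenness(c(5, 5, 5, 5)), 1)
  # counts (10, 1, 1): direct evaluation of -sum(p log p)/log S
  p <- c(10, 1, 1) / 12
  expect_equal(shannon_evenness(c(10, 1, 1)), -sum(p * log(p)) / log(3))
  expect_error(shannon_evenness(c(7)), "fewer than 2")
  expect_error(shannon_evenness(c(7, 0, 0)), "fewer than 2")
})

test_that("evenness is scale/permutation invariant and < 1 off-uniform", {
  set.seed(5)
  for (i in 1:25) {
    x <- rpois(sample(3:12, 1), 4) + 1
    e <- shannon_evenness(x)
    expect_equal(e, shannon_evenness(sample(x) * 7))
    if (length(unique(x)) > 1) expect_lt(e, 1)
    expect_gte(e, 0)
  }
})

test_that("Chao1 collapses without singletons and follows the formula", {
  expect_equal(chao1(c(3, 4, 5))$estimate, 3) # f1 = 0
  x <- c(rep(1, 4), rep(2, 2), 5, 6, 7, 8) # S=10, f1=4, f2=2
  expect_equal(chao1(x)$estimate, 10 + 16 / 4)
  expect_error(chao1(numeric(0)), "empty")
})

test_that("Chao1 estimate and SE equal an independent transcription", {
  set.seed(17)
  for (i in 1:120) {
    x <- rpois(sample(4:25, 1), sample(1:4, 1)) + rbinom(1, 1, 0.5)
    x <- x[x > 0]
    if (length(x) < 2) next
    got <- chao1(x)
    want <- bf_chao1(x)
    expect_equal(got$estimate, unname(want["est"]))
    expect_equal(got$se, unname(want["se"]))
    expect_gte(got$estimate, got$S_obs) # never below observed richness
  }
})

test_that("delta+ equals the brute-force pair mean and ignores abundance", {
  reg <- fixture_registry()
  sp <- reg$records$taxon_id[reg$records$rank == "species" &
                               reg$records$status == "valid"]
  # congeneric species: the single minimal scaled distance
  expect_equal(delta_plus(c("S1", "S2"), reg)$delta_plus, 2 / 12 * 100)
  # cross-kingdom pair: maximal scaled distance
  expect_equal(delta_plus(c("S1", "S14"), reg)$delta_plus, 100)
  # 12-species subsets vs exhaustive pair loop
  set.seed(23)
  for (i in 1:100) {
    ids <- sample(sp, sample(3:12, 1))
    expect_equal(delta_plus(ids, reg)$delta_plus, bf_delta_plus(reg, ids))
  }
  # presence/absence: duplicating the list changes nothing
  ids <- sp[1:6]
  expect_equal(delta_plus(rep(ids, 3), reg)$delta_plus,
               delta_plus(ids, reg)$delta_plus)
  expect_error(delta_plus("S1", reg), "fewer than 2")
})

test_that("delta+ agrees with vegan's taxonomic distinctness", {
  skip_if_not_installed("vegan")
  reg <- fixture_registry()
  sp <- reg$records[reg$records$rank == "species" &
                      reg$records$status == "valid", ]
  # vegan: equal-step distances from the classification table, scaled to
  # max 100, delta+ on presence/absence. The kingdom column is left out so
  # vegan's implicit root sits at kingdom height, matching the package's
  # convention that cross-kingdom pairs take the same maximum as pairs
  # sharing only their kingdom.
  cls <- sp[c("genus", "family", "order", "class", "phylum")]
  rownames(cls) <- sp$taxon_id
  d <- vegan::taxa2dist(cls, varstep = FALSE)
  comm <- matrix(1, nrow = 1, ncol = nrow(sp),
                 dimnames = list("all", sp$taxon_id))
  td <- vegan::taxondive(comm, d)
  expect_equal(delta_plus(sp$taxon_id, reg)$delta_plus,
               unname(td$Dplus), tolerance = 1e-10)
})

test_that("the funnel degenerates correctly and is reproducible", {
  reg <- fixture_registry()
  sp <- reg$records$taxon_id[reg$records$rank == "species" &
                               reg$records$status == "valid"]
  # subset size = pool size: only one subset exists
  f <- distinctness_funnel(sp, length(sp), reg, n_sim = 50, seed = 1)
  expect_equal(f$sd, 0)
  expect_equal(f$mean, delta_plus(sp, reg)$delta_plus)
  # bit-for-bit determinism under a fixed seed
  f1 <- distinctness_funnel(sp, c(4, 8), reg, n_sim = 2, seed = 99)
  f2 <- distinctness_funnel(sp, c(4, 8), reg, n_sim = 2, seed = 99)
  expect_identical(f1, f2)
  # homogeneous pool (all congeners): sd = 0 at every size
  congeners <- sp[startsWith(reg$records[sp, "name"], "Petrus")]
  fh <- distinctness_funnel(congeners, c(2, 3), reg, n_sim = 100, seed = 2)
  expect_equal(fh$sd, c(0, 0))
  expect_error(distinctness_funnel(sp, 200, reg), "exceeds")
  expect_error(distinctness_funnel(sp, 1, reg), ">= 2")
})

test_that("funnel mean converges to the pool delta+ (law of large numbers)", {
  reg <- fixture_registry()
  sp <- reg$records$taxon_id[reg$records$rank == "species" &
                               reg$records$status == "valid"]
  truth <- delta_plus(sp, reg)$delta_plus
  f <- distinctness_funnel(sp, 8, reg, n_sim = 10000, seed = 31)
  mc_se <- f$sd / sqrt(10000)
  expect_lt(abs(f$mean - truth), 3 * mc_se + 1e-9)
})

test_that("rarefaction expectation matches the closed form and oracle", {
  # full sample: expectation is observed richness, variance zero
  x <- c(5, 3, 2)
  full <- rarefy_curve(x, sum(x))
  expect_equal(full$expected_S, 3)
  expect_equal(full$sd, 0, tolerance = 1e-6)
  # one individual is one species
  expect_equal(rarefy_curve(x, 1)$expected_S, 1)
  # direct choose() transcription on 100 random vectors
  set.seed(41)
  for (i in 1:100) {
    v <- rpois(sample(3:10, 1), 3) + 1
    n <- sample(seq_len(sum(v)), 1)
    got <- rarefy_curve(v, n)
    want <- bf_rarefy(v, n)
    expect_equal(got$expected_S, unname(want["e"]))
    expect_equal(got$sd^2, unname(want["v"]), tolerance = 1e-8)
  }
  expect_error(rarefy_curve(x, 11), "exceeds")
})

test_that("rarefaction agrees with vegan and with Monte-Carlo sampling", {
  skip_if_not_installed("vegan")
  x <- c(12, 7, 5, 3, 2, 1, 1)
  sizes <- c(2, 5, 10, 20)
  got <- rarefy_curve(x, sizes)
  v <- vegan::rarefy(x, sizes, se = TRUE)
  expect_equal(got$expected_S, unname(v[".S", ]), tolerance = 1e-10)
  expect_equal(got$sd, unname(v[".se", ]), tolerance = 1e-8)

  # Monte-Carlo subsampling oracle for (5, 3, 2), n = 4
  set.seed(7)
  pool <- rep(1:3, c(5, 3, 2))
  draws <- replicate(1e5, length(unique(sample(pool, 4))))
  mc_se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(rarefy_curve(c(5, 3, 2), 4)$expected_S - mean(draws)),
            3 * mc_se)
})

test_that("the rarefaction curve is non-decreasing and concave", {
  set.seed(8)
  v <- rpois(12, 4) + 1
  sizes <- seq_len(sum(v))
  e <- rarefy_curve(v, sizes)$expected_S
  expect_true(all(diff(e) >= -1e-12))
  expect_true(all(diff(diff(e)) <= 1e-9))
})
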