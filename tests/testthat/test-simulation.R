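test_that("genotypes follow Hardy-Weinberg proportions and are reproducible", {
  cfg <- sim_config(n_individuals = 20000, maf = 0.2, seed = 1)
  set.seed(1)
  g <- simulate_genotypes(cfg)
  expect_true(all(g %in% 0:2))
  freq <- tabulate(g + 1L, 3L) / length(g)
  expect_equal(freq, c(0.64, 0.32, 0.04), tolerance = 0.02)
  set.seed(99); g1 <- simulate_genotypes(cfg)
  set.seed(99); g2 <- simulate_genotypes(cfg)
  expect_identical(g1, g2)
  expect_error(sim_config(maf = 0), "maf")
})

test_that("the metabolome model reduces to the plain model bit-exactly", {
  sp <- metabolite_spectrum("m", peaks = data.frame(position = c(2.005, 3.005),
                                                    height = c(1, 0.5)))
  cfg0 <- sim_config(n_individuals = 50, beta = 1.6, seed = 4)
  cfga <- sim_config(n_individuals = 50, beta = 1.6, n_noise = 64, alpha = 0,
                     seed = 4)
  set.seed(4); g <- simulate_genotypes(cfg0)
  set.seed(11); M0 <- simulate_metabolome(sp, g, cfg0)
  set.seed(11); Ma <- simulate_metabolome(sp, g, cfga)
  expect_identical(unclass(M0)[, ], unclass(Ma)[, ])
})

test_that("genetic noise has the requested support, off the target's bins", {
  sp <- metabolite_spectrum("m", peaks = data.frame(position = 2.005, height = 1))
  cfg <- sim_config(n_individuals = 30, beta = 1.6, n_noise = 64, alpha = 0.6,
                    seed = 5)
  set.seed(5)
  g <- simulate_genotypes(cfg)
  M <- simulate_metabolome(sp, g, cfg)
  a <- attr(M, "a")
  expect_equal(sum(a != 0), 64L)
  expect_true(all(a %in% c(-1, 0, 1)))
  h <- round_to_grid(sp, cfg$bin_width, cfg$range)
  expect_true(all(h[a != 0] == 0))
  # more noise bins than signal-free bins is impossible
  tiny <- sim_config(n_individuals = 30, beta = 1, n_noise = 30, alpha = 0.5,
                     bin_width = 0.5, seed = 5)
  expect_error(simulate_metabolome(sp, g, tiny), "exceeds")
})

test_that("without genetic effect the metabolome is standard noise", {
  sp <- metabolite_spectrum("m", peaks = data.frame(position = 2.005, height = 1))
  cfg <- sim_config(n_individuals = 2000, beta = 0, bin_width = 0.1, seed = 6)
  set.seed(6)
  g <- simulate_genotypes(cfg)
  M <- simulate_metabolome(sp, g, cfg)
  expect_equal(mean(colMeans(M)), 0, tolerance = 0.01)
  expect_equal(mean(apply(M, 2, sd)), 1, tolerance = 0.01)
})

test_that("associate reproduces the hand-computed OLS solution", {
  g <- c(0, 0, 1, 2)
  y <- matrix(c(0, 1, 1, 2), ncol = 1)
  cfg <- sim_config(n_individuals = 4, bin_width = 10, range = c(0, 10))
  ps <- associate(y, g, cfg)
  expect_equal(ps$features$beta, 2 / 2.75, tolerance = 1e-10)
  expect_equal(ps$features$se, 0.3149183, tolerance = 1e-6)
  # p agrees with the t distribution on n - 2 df
  tstat <- ps$features$beta / ps$features$se
  expect_equal(ps$features$p, 2 * pt(-abs(tstat), df = 2))
  expect_error(associate(matrix(1, 4, 1), g, cfg), "zero variance")
})

test_that("associate agrees with lm() per column", {
  set.seed(12)
  cfg <- sim_config(n_individuals = 60, bin_width = 1, seed = 12)
  g <- simulate_genotypes(cfg)
  M <- matrix(rnorm(60 * 10), 60, 10)
  M[, 3] <- M[, 3] + 0.8 * g
  ps <- associate(M, g, cfg)
  for (j in c(1, 3, 7)) {
    fit <- summary(lm(M[, j] ~ g))$coefficients
    expect_equal(ps$features$beta[j], fit["g", "Estimate"], tolerance = 1e-10)
    expect_equal(ps$features$se[j], fit["g", "Std. Error"], tolerance = 1e-10)
    expect_equal(ps$features$p[j], fit["g", "Pr(>|t|)"], tolerance = 1e-10)
  }
})

test_that("null association p-values are uniform", {
  cfg <- sim_config(n_individuals = 200, beta = 0, bin_width = 0.01, seed = 8)
  sp <- metabolite_spectrum("m", peaks = data.frame(position = 2.005, height = 1))
  set.seed(8)
  pvals <- unlist(lapply(1:10, function(r) {
    g <- simulate_genotypes(cfg)
    associate(simulate_metabolome(sp, g, cfg), g, cfg)$features$p
  }))
  # 10 replicates x 1000 features; target bin carries no effect at beta = 0
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("effect size is recovered at the signal bin", {
  cfg <- sim_config(n_individuals = 400, beta = 1.6, seed = 13)
  sp <- metabolite_spectrum("m", peaks = data.frame(position = 2.005, height = 1))
  est <- vapply(1:30, function(r) {
    set.seed(cfg$seed + r)
    g <- simulate_genotypes(cfg)
    M <- simulate_metabolome(sp, g, cfg)
    ps <- associate(M, g, cfg)
    ps$features$beta[which.max(abs(ps$features$beta))]
  }, numeric(1))
  mc_se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - 1.6), 2 * mc_se + 1e-3)
})

test_that("r90 is the nearest-rank 90th-percentile order statistic", {
  expect_equal(r90(rep(1L, 1000)), 1L)
  set.seed(2)
  expect_equal(r90(sample(1:1000)), 900L)
  expect_equal(r90(c(5L, 1L, 2L)), 5L)  # ceiling(0.9 * 3) = 3rd smallest
})

test_that("run_replicates is reproducible and r90 = 1 under a strong signal", {
  db <- generate_synthetic_db(5, seed = 14, min_gap = 0.12, n_clusters = c(1, 2))
  cfg <- sim_config(beta = 1.6, n_replicates = 10, seed = 7,
                    n_individuals = 200)
  st <- scoring_settings(delta = 0.02)
  rr1 <- run_replicates(db, "SM002", cfg, st)
  rr2 <- run_replicates(db, "SM002", cfg, st)
  expect_identical(rr1$ranks, rr2$ranks)
  expect_equal(rr1$r90, 1L)
  expect_true(all(rr1$ranks == 1L))
  expect_error(run_replicates(db, "nope", cfg, st), "not in database")
})

test_that("mean r90 does not increase with effect size", {
  db <- generate_synthetic_db(5, seed = 15)
  st <- scoring_settings(delta = 0.02)
  mean_r90 <- vapply(c(0.1, 0.4, 1.6), function(b) {
    sw <- performance_sweep(db, sim_config(beta = b, n_replicates = 10,
                                           n_individuals = 200, seed = 16), st)
    mean(sw$table$r90)
  }, numeric(1))
  expect_true(mean_r90[1] >= mean_r90[2] - 0.5)
  expect_true(mean_r90[2] >= mean_r90[3] - 0.5)
  expect_gt(mean_r90[1], mean_r90[3])
})

test_that("the synthetic database generator is deterministic and coherent", {
  db1 <- generate_synthetic_db(180, seed = 42)
  expect_length(db1$spectra, 180L)
  expect_equal(anyDuplicated(db_ids(db1)), 0L)
  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_spectral_db(db1, p1)
  write_spectral_db(generate_synthetic_db(180, seed = 42), p2)
  expect_identical(readLines(p1), readLines(p2))
  # every multiplet range encloses peaks, and max height is 1
  for (sp in db1$spectra[1:20]) {
    expect_equal(max(sp$peaks$height), 1)
    covered <- vapply(sp$peaks$position, function(p)
      any(p >= sp$multiplets$low & p <= sp$multiplets$high), logical(1))
    expect_true(all(covered))
  }
})

test_that("performance_sweep flags degenerate correlations", {
  # two identical spectra: no variance in spectrum size
  sp <- data.frame(position = c(2.005, 2.015), height = c(1, 0.5))
  db <- spectral_db(list(metabolite_spectrum("a", peaks = sp),
                         metabolite_spectrum("b", peaks = sp)))
  sw <- performance_sweep(db, sim_config(beta = 1.6, n_replicates = 5,
                                         n_individuals = 100, seed = 18),
                          scoring_settings(delta = 0.02))
  expect_true(sw$correlations$degenerate)
  expect_true(is.na(sw$correlations$cor_r90_size))
})
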