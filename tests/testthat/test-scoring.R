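# a two-feature pseudospectrum whose match set covers both features
two_feature_case <- function(beta = c(3, 4), se = 1) {
  ps <- make_ps(c(2.005, 2.015), beta = beta, se = se)
  sp <- metabolite_spectrum("m", peaks = data.frame(position = 2.01, height = 1))
  list(ps = ps, ms = build_match_set(sp, ps, delta = 0.03, mode = "peak"))
}

test_that("chi-squared score matches the closed form", {
  cs <- two_feature_case(beta = c(3, 4))
  # T = 25 on 2 df: survival function exp(-T/2)
  expect_equal(chi2_score(cs$ps, cs$ms), -log10(exp(-12.5)), tolerance = 1e-10)
  # single feature with beta = 0 scores 0
  ps0 <- make_ps(2.005, beta = 0)
  sp <- metabolite_spectrum("m", peaks = data.frame(position = 2.005, height = 1))
  expect_equal(chi2_score(ps0, build_match_set(sp, ps0, 0.01)), 0)
})

test_that("Z score matches the normal-tail oracle and cancels opposite signs", {
  cs <- two_feature_case(beta = c(3, 4))
  # Z = 7, sd = sqrt(2)
  expect_equal(z_score(cs$ps, cs$ms),
               -log10(2 * pnorm(-7 / sqrt(2))), tolerance = 1e-10)
  expect_equal(z_score(cs$ps, cs$ms), 6.129, tolerance = 1e-3)
  cancel <- two_feature_case(beta = c(3, -3))
  expect_equal(z_score(cancel$ps, cancel$ms), 0)
})

test_that("singleton match sets give identical chi-squared and Z scores", {
  for (b in c(-4.2, -1, 0.3, 2, 7)) {
    ps <- make_ps(2.005, beta = b)
    sp <- metabolite_spectrum("m", peaks = data.frame(position = 2.005, height = 1))
    ms <- build_match_set(sp, ps, 0.01)
    expect_equal(z_score(ps, ms), chi2_score(ps, ms), tolerance = 1e-12)
    expect_equal(chi2_score(ps, ms), -log10(2 * pnorm(-abs(b))),
                 tolerance = 1e-12)
  }
})

test_that("scores stay accurate far beyond double-precision p-values", {
  ps <- make_ps(2.005, beta = 40)  # two-sided p ~ 1e-350
  sp <- metabolite_spectrum("m", peaks = data.frame(position = 2.005, height = 1))
  ms <- build_match_set(sp, ps, 0.01)
  expect_gt(chi2_score(ps, ms), 300)
  expect_true(is.finite(chi2_score(ps, ms)))
  expect_equal(chi2_score(ps, ms), z_score(ps, ms), tolerance = 1e-9)
})

test_that("decorrelated scores reduce exactly to plain scores", {
  cs <- two_feature_case(beta = c(3, 4))
  C_id <- correlation_matrix(cs$ps$features$position, diag(2))
  C_cor <- correlation_matrix(cs$ps$features$position,
                              matrix(c(1, 0.8, 0.8, 1), 2))
  # lambda = 1: any correlation matrix
  expect_identical(chi2_score_decorrelated(cs$ps, cs$ms, C_cor, 1),
                   chi2_score(cs$ps, cs$ms))
  expect_identical(z_score_decorrelated(cs$ps, cs$ms, C_cor, 1),
                   z_score(cs$ps, cs$ms))
  # identity correlation: any lambda
  for (lam in c(0.2, 0.5, 0.9)) {
    expect_equal(chi2_score_decorrelated(cs$ps, cs$ms, C_id, lam),
                 chi2_score(cs$ps, cs$ms), tolerance = 1e-12)
    expect_equal(z_score_decorrelated(cs$ps, cs$ms, C_id, lam),
                 z_score(cs$ps, cs$ms), tolerance = 1e-12)
  }
})

test_that("decorrelated quadratic form matches a hand-inverted 2x2 block", {
  cs <- two_feature_case(beta = c(3, 3))
  C_cor <- correlation_matrix(cs$ps$features$position,
                              matrix(c(1, 0.8, 0.8, 1), 2))
  # shrunk block at lambda = 0.5 is [[1, 0.4], [0.4, 1]]
  u <- c(3, 3)
  qf <- drop(u %*% solve(matrix(c(1, 0.4, 0.4, 1), 2), u))
  expect_equal(chi2_score_decorrelated(cs$ps, cs$ms, C_cor, 0.5),
               -pchisq(qf, 2, lower.tail = FALSE, log.p = TRUE) / log(10),
               tolerance = 1e-12)
  # Z variance: 2 + 2 * 0.5 * 0.8 = 2.8
  expect_equal(z_score_decorrelated(cs$ps, cs$ms, C_cor, 0.5),
               -log10(2 * pnorm(-6 / sqrt(2.8))), tolerance = 1e-12)
})

test_that("block-diagonal quadratic form equals the dense-matrix oracle", {
  set.seed(11)
  for (rep in 1:12) {
    # random positions in two well-separated clumps => nontrivial blocks;
    # spacings stay above the 1e-4 ppm storage resolution
    pos <- sort(c(1 + cumsum(runif(3, 0.005, 0.02)),
                  5 + cumsum(runif(2, 0.005, 0.02))))
    ps <- make_ps(pos, beta = rnorm(5, sd = 2))
    sp <- metabolite_spectrum("m", peaks = data.frame(
      position = c(1.02, 5.02), height = c(1, 0.8)))
    ms <- build_match_set(sp, ps, delta = 0.04)
    A <- matrix(rnorm(25), 5); S <- cov2cor(crossprod(A) + diag(5))
    C_hat <- correlation_matrix(pos, S)
    lam <- runif(1, 0.3, 0.9)
    # dense construction over the matched features: (1-lam) C J + lam I
    idx <- ms$feature_idx
    J <- matrix(0, length(idx), length(idx))
    for (b in ms$blocks) {
      w <- match(b, idx)
      J[w, w] <- 1
    }
    Cd <- (1 - lam) * S[idx, idx] * J + lam * diag(length(idx))
    u <- (ps$features$beta / ps$features$se)[idx]
    qf <- drop(u %*% solve(Cd, u))
    expect_equal(chi2_score_decorrelated(ps, ms, C_hat, lam),
                 -pchisq(qf, length(idx), lower.tail = FALSE,
                         log.p = TRUE) / log(10),
                 tolerance = 1e-9)
    expect_equal(z_score_decorrelated(ps, ms, C_hat, lam),
                 -log10(2 * pnorm(-abs(sum(u)) / sqrt(abs(sum(Cd))))),
                 tolerance = 1e-9)
  }
})

test_that("scores are invariant to feature order and to rescaling", {
  set.seed(5)
  pos <- sort(runif(6, 2, 2.1))
  beta <- rnorm(6); se <- runif(6, 0.5, 2)
  sp <- metabolite_spectrum("m", peaks = data.frame(position = 2.05, height = 1))
  ps1 <- make_ps(pos, beta, se)
  ms1 <- build_match_set(sp, ps1, 0.08)
  # rescaling all beta and se by the same constant changes nothing
  ps2 <- make_ps(pos, 3.7 * beta, 3.7 * se)
  ms2 <- build_match_set(sp, ps2, 0.08)
  expect_equal(chi2_score(ps2, ms2), chi2_score(ps1, ms1), tolerance = 1e-12)
  expect_equal(z_score(ps2, ms2), z_score(ps1, ms1), tolerance = 1e-12)
  # permuting the input rows changes nothing (constructor re-sorts)
  perm <- sample(6)
  ps3 <- make_ps(pos[perm], beta[perm], se[perm])
  ms3 <- build_match_set(sp, ps3, 0.08)
  expect_equal(chi2_score(ps3, ms3), chi2_score(ps1, ms1))
})

test_that("scores are continuous in lambda on (0, 1]", {
  cs <- two_feature_case(beta = c(2, 3))
  C_cor <- correlation_matrix(cs$ps$features$position,
                              matrix(c(1, 0.6, 0.6, 1), 2))
  lams <- seq(0.05, 1, by = 0.05)
  sc <- vapply(lams, function(l)
    chi2_score_decorrelated(cs$ps, cs$ms, C_cor, l), numeric(1))
  expect_true(all(abs(diff(sc)) < 0.5))
  expect_equal(sc[length(sc)], chi2_score(cs$ps, cs$ms))
})

test_that("scoring_settings validates its arguments", {
  expect_error(scoring_settings(lambda = 0), "lambda")
  expect_equal(scoring_settings(mode = "multiplet")$delta, 0.01)
  expect_equal(scoring_settings()$delta, 0.03)
})

test_that("score_database enumerates variants correctly", {
  db <- generate_synthetic_db(4, seed = 2, n_clusters = c(1, 2))
  ps <- noise_ps(seed = 3)
  tab1 <- score_database(ps, db, scoring_settings())
  expect_equal(nrow(tab1), 4L)
  tab2 <- score_database(ps, db, scoring_settings(variant = "2c"))
  expect_equal(nrow(tab2), choose(4, 2) + 4L)  # unordered pairs + self-pairs
  # a self-pair scores exactly like the single metabolite
  for (id in db_ids(db)) {
    expect_equal(tab2$score[tab2$candidate == id],
                 tab1$score[tab1$candidate == id])
  }
  # pm on an all-positive pseudospectrum: '+' sub-table equals the 1c table
  ps_pos <- make_ps(grid_centers()[1:50], beta = abs(rnorm(50)) + 0.01)
  tp <- score_database(ps_pos, db, scoring_settings(variant = "pm"))
  t1 <- score_database(ps_pos, db, scoring_settings())
  plus <- tp[tp$direction == "+", c("candidate", "score", "rank")]
  expect_equal(plus$score[order(plus$candidate)],
               t1$score[order(t1$candidate)])
})

test_that("a metabolite whose peaks carry the signal ranks first", {
  sp1 <- metabolite_spectrum("target", peaks = data.frame(
    position = c(2.005, 2.505), height = c(1, 0.5)))
  sp2 <- metabolite_spectrum("decoy", peaks = data.frame(
    position = c(7.005, 8.005), height = c(1, 0.8)))
  db <- spectral_db(list(sp1, sp2))
  grid <- grid_centers()
  beta <- numeric(length(grid))
  beta[abs(grid - 2.005) < 1e-9 | abs(grid - 2.505) < 1e-9] <- 6
  ps <- make_ps(grid, beta)
  tab <- score_database(ps, db, scoring_settings())
  expect_equal(tab$candidate[tab$rank == 1], "target")
  expect_equal(reference_rank(tab, "target"), 1L)
})

test_that("decorrelation without a correlation matrix is rejected", {
  db <- tiny_db()
  ps <- noise_ps(4)
  expect_error(score_database(ps, db, scoring_settings(lambda = 0.5)),
               "correlation")
})

test_that("empty match sets are flagged, scored 0, and ranked last", {
  far <- metabolite_spectrum("far", peaks = data.frame(position = 11.5, height = 1))
  near <- metabolite_spectrum("near", peaks = data.frame(position = 2.005, height = 1))
  db <- spectral_db(list(far, near))
  ps <- make_ps(c(2.005, 2.015), beta = c(3, 1))
  tab <- score_database(ps, db, scoring_settings())
  row <- tab[tab$candidate == "far", ]
  expect_equal(row$score, 0)
  expect_equal(row$flags, "empty_match_set")
  expect_equal(row$rank, 2L)
  expect_equal(nrow(tab), 2L)  # output keeps one row per candidate
})

test_that("score table TSV round-trips the ranking", {
  db <- tiny_db()
  ps <- noise_ps(8)
  tab <- score_database(ps, db, scoring_settings())
  path <- withr::local_tempfile(fileext = ".tsv")
  write_score_table(tab, path)
  lines <- readLines(path)
  expect_true(any(grepl("^# settings:", lines)))
  back <- read.delim(path, comment.char = "#")
  expect_equal(back$candidate, tab$candidate)
  expect_equal(back$rank, tab$rank)
})
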