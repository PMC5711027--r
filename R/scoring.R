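#' Scoring settings
#'
#' Bundles the axes along which a scoring run is configured: match-set mode
#' and neighborhood parameter, the match statistic, the shrinkage parameter
#' of the decorrelation, and the candidate-enumeration variant.
#'
#' @param mode match-set mode, `"peak"` or `"multiplet"`.
#' @param scoring match statistic: `"chi2"` (sum of squared `beta/se`,
#'   referred to a chi-squared distribution) or `"z"` (sum of `beta/se`,
#'   referred to a normal distribution).
#' @param delta neighborhood parameter in ppm. Defaults to 0.03 in peak mode
#'   and 0.01 in multiplet mode.
#' @param lambda shrinkage parameter in (0, 1]: the decorrelation mixes the
#'   empirical feature correlation with the identity as
#'   `(1 - lambda) * C_hat * J + lambda * I` within feature neighborhoods.
#'   `lambda = 1` disables decorrelation (the default); `lambda = 0` is
#'   rejected because unshrunk empirical correlation blocks can be singular
#'   and let candidates acquire artificially high scores.
#' @param variant candidate enumeration: `"1c"` (each metabolite), `"2c"`
#'   (every unordered metabolite pair, self-pairs included), `"pm"`
#'   (directional: each metabolite scored separately per effect direction)
#'   or `"pm2c"` (pairs per direction).
#' @param pm_p_threshold p-value threshold used by the directional split
#'   (see [split_by_direction()]).
#' @param z_tail tail convention for Z-scoring: `"two_sided"` (default,
#'   invariant to a global allele-coding flip and consistent with chi-squared
#'   scoring on singleton match sets) or `"one_sided"`.
#' @return An object of class `scoring_settings`.
#' @export
scoring_settings <- function(mode = c("peak", "multiplet"),
                             scoring = c("chi2", "z"),
                             delta = NULL,
                             lambda = 1,
                             variant = c("1c", "2c", "pm", "pm2c"),
                             pm_p_threshold = 1e-6,
                             z_tail = c("two_sided", "one_sided")) {
  mode <- match.arg(mode)
  scoring <- match.arg(scoring)
  variant <- match.arg(variant)
  z_tail <- match.arg(z_tail)
  if (is.null(delta)) delta <- if (mode == "peak") 0.03 else 0.01
  stopifnot(delta >= 0, lambda >= 0, lambda <= 1,
            pm_p_threshold > 0, pm_p_threshold < 1)
  if (lambda == 0) {
    stop("lambda = 0 (no shrinkage) is not allowed: empirical correlation ",
         "blocks can be singular; use lambda > 0", call. = FALSE)
  }
  structure(list(mode = mode, scoring = scoring, delta = delta,
                 lambda = lambda, variant = variant,
                 pm_p_threshold = pm_p_threshold, z_tail = z_tail),
            class = "scoring_settings")
}

#' @export
print.scoring_settings <- function(x, ...) {
  cat(sprintf("<scoring_settings> %s mode, %s scoring, delta=%g, lambda=%g, variant=%s\n",
              x$mode, x$scoring, x$delta, x$lambda, x$variant))
  invisible(x)
}

format_settings <- function(s) {
  sprintf("mode=%s scoring=%s delta=%g lambda=%g variant=%s pm_p_threshold=%g",
          s$mode, s$scoring, s$delta, s$lambda, s$variant, s$pm_p_threshold)
}

# -log10 of the chi-squared survival function, evaluated in log space so that
# scores of several hundred (p ~ 1e-300 and below) stay finite and accurate
chi2_neglog10_sf <- function(stat, df) {
  -stats::pchisq(stat, df = df, lower.tail = FALSE, log.p = TRUE) / log(10)
}

# -log10 of the two-sided (or one-sided) normal tail of z; log space as above
norm_neglog10_tail <- function(z, sd, two_sided = TRUE) {
  logp <- stats::pnorm(abs(z) / sd, lower.tail = FALSE, log.p = TRUE)
  if (two_sided) logp <- logp + log(2)
  -logp / log(10)
}

ps_t <- function(ps) ps$features$beta / ps$features$se

#' Chi-squared match score
#'
#' Computes the match sum `T = sum over matched features of (beta/se)^2`,
#' refers it to a chi-squared distribution with as many degrees of freedom as
#' matched features, and returns the score `-log10(p)`. Tail probabilities
#' are evaluated in log space, so scores of several hundred (p-values far
#' below double precision) are exact.
#'
#' An empty match set yields score 0 (flagged downstream); the null
#' calibration assumes independent features, which the companion simulation
#' framework satisfies by construction, while real pseudospectra do not —
#' scores rank candidates within a pseudospectrum and carry no significance.
#'
#' @param ps a [pseudospectrum()].
#' @param ms a [build_match_set()] result for `ps`.
#' @return Non-negative numeric score.
#' @export
chi2_score <- function(ps, ms) {
  stopifnot(inherits(ps, "pseudospectrum"), inherits(ms, "match_set"))
  k <- length(ms$feature_idx)
  if (k == 0L) return(0)
  t <- ps_t(ps)[ms$feature_idx]
  chi2_neglog10_sf(sum(t^2), k)
}

#' Z match score
#'
#' Computes the signed match sum `Z = sum over matched features of beta/se`,
#' treated under the null as normal with mean zero and variance equal to the
#' number of matched features. The score is `-log10` of the two-sided tail of
#' `|Z|` by default (see `z_tail` in [scoring_settings()]). Opposite-direction
#' effects within the match set cancel, which is the point of Z-scoring:
#' it rewards coherent effect directions across a spectrum's peaks.
#'
#' @inheritParams chi2_score
#' @param two_sided use the two-sided tail (default TRUE).
#' @return Non-negative numeric score.
#' @export
z_score <- function(ps, ms, two_sided = TRUE) {
  stopifnot(inherits(ps, "pseudospectrum"), inherits(ms, "match_set"))
  k <- length(ms$feature_idx)
  if (k == 0L) return(0)
  t <- ps_t(ps)[ms$feature_idx]
  norm_neglog10_tail(sum(t), sqrt(k), two_sided = two_sided)
}

# shrunk within-block correlation: (1 - lambda) C_hat + lambda I on a
# neighborhood block; off-block entries of the full C_delta are zero off the
# diagonal, so the matrix is block diagonal over ms$blocks
shrunk_block <- function(C_hat_values, block_idx, lambda) {
  B <- C_hat_values[block_idx, block_idx, drop = FALSE]
  (1 - lambda) * B + lambda * diag(length(block_idx))
}

#' Decorrelated chi-squared match score
#'
#' Replaces the plain sum of squares by the quadratic form
#' `t' C^{-1} t` where `C` is the block-diagonal decorrelation matrix:
#' within each feature neighborhood, the shrunk empirical correlation
#' `(1 - lambda) C_hat + lambda I`; zero between neighborhoods. The quadratic
#' form is referred to a chi-squared distribution with `|F|` degrees of
#' freedom. At `lambda = 1`, or when `C_hat` is the identity, this reproduces
#' [chi2_score()] exactly.
#'
#' @inheritParams chi2_score
#' @param C_hat a [correlation_matrix()] aligned to `ps`.
#' @param lambda shrinkage parameter in (0, 1].
#' @return Non-negative numeric score.
#' @export
chi2_score_decorrelated <- function(ps, ms, C_hat, lambda = 0.5) {
  stopifnot(inherits(ps, "pseudospectrum"), inherits(ms, "match_set"),
            inherits(C_hat, "correlation_matrix"),
            lambda > 0, lambda <= 1)
  k <- length(ms$feature_idx)
  if (k == 0L) return(0)
  if (nrow(C_hat$values) != nrow(ps$features)) {
    stop("correlation matrix does not match pseudospectrum dimension",
         call. = FALSE)
  }
  t_all <- ps_t(ps)
  qf <- 0
  for (block in ms$blocks) {
    tb <- t_all[block]
    Cb <- shrunk_block(C_hat$values, block, lambda)
    sol <- tryCatch(solve(Cb, tb), error = function(e)
      stop("singular decorrelation block; increase lambda above ", lambda,
           call. = FALSE))
    qf <- qf + sum(tb * sol)
  }
  chi2_neglog10_sf(qf, k)
}

#' Decorrelated Z match score
#'
#' The match sum `Z = sum beta/se` is unchanged; decorrelation instead
#' adjusts the null variance to `|sum of all entries of C|` with `C` the
#' block-diagonal decorrelation matrix of [chi2_score_decorrelated()].
#' Off-block pairs contribute 0, so the variance is the sum of the entries of
#' the shrunk blocks. At `lambda = 1` or `C_hat = I` the variance is `|F|`,
#' reproducing [z_score()].
#'
#' @inheritParams chi2_score_decorrelated
#' @param two_sided use the two-sided tail (default TRUE).
#' @return Non-negative numeric score.
#' @export
z_score_decorrelated <- function(ps, ms, C_hat, lambda = 0.5, two_sided = TRUE) {
  stopifnot(inherits(ps, "pseudospectrum"), inherits(ms, "match_set"),
            inherits(C_hat, "correlation_matrix"),
            lambda > 0, lambda <= 1)
  k <- length(ms$feature_idx)
  if (k == 0L) return(0)
  if (nrow(C_hat$values) != nrow(ps$features)) {
    stop("correlation matrix does not match pseudospectrum dimension",
         call. = FALSE)
  }
  t_all <- ps_t(ps)
  v <- 0
  for (block in ms$blocks) {
    v <- v + sum(shrunk_block(C_hat$values, block, lambda))
  }
  v <- abs(v)
  if (v <= 0) stop("non-positive decorrelated variance", call. = FALSE)
  norm_neglog10_tail(sum(t_all[ms$feature_idx]), sqrt(v), two_sided = two_sided)
}

score_one <- function(ps, ms, settings, C_hat = NULL) {
  decor <- settings$lambda < 1 && !is.null(C_hat)
  two_sided <- settings$z_tail == "two_sided"
  if (settings$scoring == "chi2") {
    if (decor) chi2_score_decorrelated(ps, ms, C_hat, settings$lambda)
    else chi2_score(ps, ms)
  } else {
    if (decor) z_score_decorrelated(ps, ms, C_hat, settings$lambda,
                                    two_sided = two_sided)
    else z_score(ps, ms, two_sided = two_sided)
  }
}

#' Score every candidate in a spectral database against a pseudospectrum
#'
#' Enumerates candidates according to the settings variant — single
#' metabolites (`1c`), unordered pairs including self-pairs scored on the
#' union of their match sets (`2c`), per-direction tables after the
#' directional split (`pm`), or pairs per direction (`pm2c`) — scores each
#' candidate, and returns a ranked score table. Candidates with empty match
#' sets receive score 0, are flagged, and rank after all scored candidates.
#'
#' @param ps a [pseudospectrum()].
#' @param db a [spectral_db()].
#' @param settings a [scoring_settings()].
#' @param C_hat optional [correlation_matrix()]; required when
#'   `settings$lambda < 1`.
#' @return A `score_table`: a `data.frame` with columns `rank`, `candidate`,
#'   `direction`, `score`, `n_features`, `dof_or_variance`, `flags`, carrying
#'   the settings as an attribute.
#' @export
score_database <- function(ps, db, settings = scoring_settings(), C_hat = NULL) {
  stopifnot(inherits(ps, "pseudospectrum"), inherits(db, "spectral_db"),
            inherits(settings, "scoring_settings"))
  if (settings$lambda < 1 && is.null(C_hat)) {
    stop("decorrelation (lambda < 1) requires a feature correlation matrix",
         call. = FALSE)
  }
  if (settings$variant %in% c("pm", "pm2c")) {
    halves <- split_by_direction(ps, settings$pm_p_threshold)
    sub_variant <- if (settings$variant == "pm") "1c" else "2c"
    sub_settings <- settings
    sub_settings$variant <- sub_variant
    # each direction is ranked as its own sub-table
    tab_p <- rank_scores(score_database_flat(halves$plus, db, sub_settings,
                                             C_hat, "+"))
    tab_m <- rank_scores(score_database_flat(halves$minus, db, sub_settings,
                                             C_hat, "-"))
    tab <- rbind(tab_p, tab_m)
  } else {
    tab <- rank_scores(score_database_flat(ps, db, settings, C_hat, "na"))
  }
  attr(tab, "settings") <- settings
  attr(tab, "variant_id") <- ps$variant_id
  class(tab) <- c("score_table", "data.frame")
  tab
}

# one direction, variant 1c or 2c; returns an unranked table
score_database_flat <- function(ps, db, settings, C_hat, direction) {
  spectra <- db$spectra
  match_sets <- lapply(spectra, function(sp)
    suppressWarnings(build_match_set(sp, ps, settings$delta, settings$mode)))
  ids <- names(spectra)
  if (settings$variant == "1c") {
    cand_sets <- match_sets
    cand_names <- ids
  } else {
    pairs <- which(upper.tri(diag(length(ids)), diag = TRUE), arr.ind = TRUE)
    cand_sets <- lapply(seq_len(nrow(pairs)), function(r) {
      i <- pairs[r, "row"]; j <- pairs[r, "col"]
      if (i == j) match_sets[[i]] else
        pair_match_set(match_sets[[i]], match_sets[[j]])
    })
    cand_names <- vapply(seq_len(nrow(pairs)), function(r) {
      i <- pairs[r, "row"]; j <- pairs[r, "col"]
      if (i == j) ids[i] else paste(ids[i], ids[j], sep = "+")
    }, character(1))
  }
  scores <- vapply(cand_sets, function(ms) score_one(ps, ms, settings, C_hat),
                   numeric(1))
  n_feat <- vapply(cand_sets, function(ms) length(ms$feature_idx), integer(1))
  dv <- vapply(cand_sets, function(ms)
    dof_or_variance(ms, settings, C_hat), numeric(1))
  flags <- ifelse(n_feat == 0L,
                  ifelse(vapply(cand_sets, `[[`, logical(1),
                                "missing_description"),
                         "missing_description", "empty_match_set"), "")
  data.frame(rank = NA_integer_, candidate = cand_names, direction = direction,
             score = scores, n_features = n_feat, dof_or_variance = dv,
             flags = flags, stringsAsFactors = FALSE)
}

dof_or_variance <- function(ms, settings, C_hat) {
  k <- length(ms$feature_idx)
  if (k == 0L) return(0)
  if (settings$scoring == "chi2") return(as.numeric(k))
  if (settings$lambda < 1 && !is.null(C_hat)) {
    v <- 0
    for (block in ms$blocks) {
      v <- v + sum(shrunk_block(C_hat$values, block, settings$lambda))
    }
    abs(v)
  } else {
    as.numeric(k)
  }
}

#' @export
print.score_table <- function(x, n = 10L, ...) {
  s <- attr(x, "settings")
  if (!is.null(s)) cat("# ", format_settings(s), "\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), n), row.names = FALSE)
  if (nrow(x) > n) cat(sprintf("# ... %d more candidate(s)\n", nrow(x) - n))
  invisible(x)
}

#' Write a ranked score table as TSV
#'
#' Settings are echoed in `#` comment header lines, so a run can be
#' reproduced from its output alone.
#'
#' @param table a `score_table` from [score_database()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_score_table <- function(table, path) {
  stopifnot(inherits(table, "score_table"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  s <- attr(table, "settings")
  if (!is.null(s)) writeLines(paste0("# settings: ", format_settings(s)), con)
  v <- attr(table, "variant_id")
  if (!is.null(v)) writeLines(paste0("# variant: ", v), con)
  df <- as.data.frame(table)
  df$score <- formatC(df$score, format = "g", digits = 10)
  df$dof_or_variance <- formatC(df$dof_or_variance, format = "g", digits = 10)
  writeLines(paste(names(df), collapse = "\t"), con)
  writeLines(do.call(paste, c(df, sep = "\t")), con)
  invisible(path)
}
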