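#' Simulation configuration
#'
#' Study conditions for the simulation framework: a cohort of `n_individuals`
#' genotyped at a biallelic variant with minor allele frequency `maf`, and a
#' binned NMR metabolome over `range` at `bin_width` resolution in which the
#' variant shifts the target metabolite's binned spectrum by `beta` per
#' allele against unit-variance noise. Genetic noise adds `n_noise` extra
#' bins that also respond to the genotype with amplitude `alpha * beta` and
#' random sign.
#'
#' @param n_individuals cohort size (default 400).
#' @param maf minor allele frequency in (0, 1) (default 0.2).
#' @param beta per-allele effect size on binned spectrum heights (noise has
#'   unit variance, so `beta` is in noise-sd units).
#' @param n_noise number of genetic-noise bins `N_a` (default 0: the plain
#'   model).
#' @param alpha genetic-noise amplitude in \[0, 1).
#' @param bin_width bin width in ppm (default 0.01).
#' @param range binned chemical-shift range (default `c(0, 10)`).
#' @param n_replicates replicates per metabolite for rank percentiles
#'   (default 1000).
#' @param seed base RNG seed; replicate `r` uses `seed + r` so any replicate
#'   is reproducible in isolation.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 400, maf = 0.2, beta = 1,
                       n_noise = 0, alpha = 0, bin_width = 0.01,
                       range = c(0, 10), n_replicates = 1000, seed = 1) {
  stopifnot(n_individuals >= 3, maf > 0, maf < 1,
            n_noise >= 0, alpha >= 0, alpha < 1,
            bin_width > 0, length(range) == 2L, range[1] < range[2],
            n_replicates >= 1)
  structure(list(n_individuals = as.integer(n_individuals), maf = maf,
                 beta = beta, n_noise = as.integer(n_noise), alpha = alpha,
                 bin_width = bin_width, range = range,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate genotypes under Hardy-Weinberg equilibrium
#'
#' Each individual's genotype in \{0, 1, 2\} is the sum of two independent
#' Bernoulli(maf) allele draws. A monomorphic draw (no genotype variance,
#' possible for small cohorts) is redrawn up to `max_retries` times.
#'
#' @param cfg a [sim_config()].
#' @param max_retries redraw budget for monomorphic vectors.
#' @return Integer vector of length `cfg$n_individuals`.
#' @export
simulate_genotypes <- function(cfg, max_retries = 100L) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- cfg$n_individuals
  for (attempt in seq_len(max_retries + 1L)) {
    g <- stats::rbinom(n, 1L, cfg$maf) + stats::rbinom(n, 1L, cfg$maf)
    if (stats::var(g) > 0) return(g)
  }
  stop("genotype vector monomorphic after ", max_retries, " redraws",
       call. = FALSE)
}

#' Simulate a feature metabolome for one target metabolite
#'
#' Builds the individuals-by-bins matrix
#' `M[i, j] = beta * h[j] * g[i] + alpha * beta * g[i] * a[j] + e[i, j]`
#' with `h` the target spectrum rounded to the binning grid, `e` iid standard
#' normal, and `a` the genetic-noise support: `n_noise` bins drawn uniformly
#' without replacement among bins where `h = 0` (so noise never aliases the
#' target's own peaks), each with a uniform random sign. With `n_noise = 0`
#' or `alpha = 0` the noise term vanishes and the plain model is reproduced
#' bit-exactly under a shared seed (the noise support is only drawn when both
#' are nonzero).
#'
#' @param spectrum the target [metabolite_spectrum()].
#' @param g genotype vector from [simulate_genotypes()].
#' @param cfg a [sim_config()].
#' @return Numeric matrix `n_individuals x n_bins` with attribute `"a"`
#'   (the genetic-noise coefficient vector).
#' @export
simulate_metabolome <- function(spectrum, g, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  h <- round_to_grid(spectrum, cfg$bin_width, cfg$range)
  n <- length(g)
  nb <- length(h)
  M <- matrix(stats::rnorm(n * nb), nrow = n, ncol = nb)
  a <- numeric(nb)
  if (cfg$n_noise > 0L && cfg$alpha > 0) {
    zero_bins <- which(h == 0)
    if (cfg$n_noise > length(zero_bins)) {
      stop("n_noise (", cfg$n_noise, ") exceeds the ", length(zero_bins),
           " bins free of target signal", call. = FALSE)
    }
    support <- sample(zero_bins, cfg$n_noise)
    a[support] <- sample(c(-1, 1), cfg$n_noise, replace = TRUE)
  }
  effect <- cfg$beta * h + cfg$alpha * cfg$beta * a
  M <- M + g %*% t(effect)
  attr(M, "a") <- a
  M
}

#' Per-feature association of a metabolome with a genotype
#'
#' Regresses every metabolome bin on the genotype by ordinary least squares
#' and assembles the resulting summary statistics into a pseudospectrum:
#' effect size `S_xy / S_xx`, standard error `sqrt(SSR / (n - 2) / S_xx)`,
#' two-sided p-value from the t distribution with `n - 2` degrees of
#' freedom. Feature positions are the bin centers.
#'
#' @param M metabolome matrix (individuals x bins).
#' @param g genotype vector; must be non-degenerate.
#' @param cfg a [sim_config()] (supplies the bin grid).
#' @param variant_id id string for the resulting pseudospectrum.
#' @return A [pseudospectrum()].
#' @export
associate <- function(M, g, cfg, variant_id = "sim") {
  stopifnot(is.matrix(M), nrow(M) == length(g))
  n <- length(g)
  if (n < 3) stop("need at least 3 individuals", call. = FALSE)
  if (stats::var(g) == 0) stop("genotype vector is degenerate", call. = FALSE)
  gc <- g - mean(g)
  sxx <- sum(gc^2)
  beta_hat <- as.numeric(crossprod(M, gc)) / sxx
  ybar <- colMeans(M)
  syy <- colSums(M^2) - n * ybar^2
  ssr <- pmax(syy - beta_hat^2 * sxx, 0)
  if (any(syy <= 0)) stop("constant metabolome column (zero variance)",
                          call. = FALSE)
  se <- sqrt(ssr / (n - 2) / sxx)
  # a perfect fit gives SSR = 0; floor the SE at machine-epsilon scale
  perfect <- se <= 0
  if (any(perfect)) se[perfect] <- sqrt(.Machine$double.eps) * abs(beta_hat[perfect])
  tstat <- beta_hat / se
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p <- pmax(p, .Machine$double.xmin)
  pseudospectrum(variant_id, data.frame(
    position = grid_centers(cfg$bin_width, cfg$range),
    beta = beta_hat, se = se, p = p))
}

#' Replicate ranks and the r90 statistic for one target metabolite
#'
#' For each replicate: draw a fresh genotype vector and metabolome for the
#' target metabolite, associate, score the full database against the
#' resulting pseudospectrum, and record the target's rank. The summary
#' statistic `r90` is the 90th-percentile rank over replicates, computed as
#' the nearest-rank order statistic (the `ceiling(0.9 * R)`-th of the sorted
#' ranks); identification is deemed successful when `r90 = 1`. Replicate `r`
#' reseeds the RNG at `cfg$seed + r`, so any replicate is reproducible in
#' isolation and replicate streams are paired across configurations sharing
#' a seed.
#'
#' @param db the [spectral_db()] of candidate spectra.
#' @param target_id id of the metabolite whose signal is simulated.
#' @param cfg a [sim_config()].
#' @param settings a [scoring_settings()].
#' @param use_correlation when `settings$lambda < 1`, estimate the feature
#'   correlation matrix from each replicate's metabolome (sample correlation
#'   of the columns of `M`).
#' @return An object of class `replicate_result`: list with `metabolite_id`,
#'   `ranks` and `r90`.
#' @export
run_replicates <- function(db, target_id, cfg, settings = scoring_settings(),
                           use_correlation = FALSE) {
  stopifnot(inherits(db, "spectral_db"), inherits(cfg, "sim_config"),
            inherits(settings, "scoring_settings"))
  if (!target_id %in% db_ids(db)) {
    stop("target '", target_id, "' not in database", call. = FALSE)
  }
  if (settings$variant != "1c") {
    stop("replicate simulation supports the 1c variant", call. = FALSE)
  }
  positions <- grid_centers(cfg$bin_width, cfg$range)
  # the bin grid is fixed, so match sets are invariant across replicates
  match_sets <- lapply(db$spectra, function(sp)
    suppressWarnings(build_match_set(sp, positions, settings$delta,
                                     settings$mode)))
  target <- db$spectra[[target_id]]
  ranks <- integer(cfg$n_replicates)
  for (r in seq_len(cfg$n_replicates)) {
    set.seed(cfg$seed + r)
    g <- simulate_genotypes(cfg)
    M <- simulate_metabolome(target, g, cfg)
    ps <- associate(M, g, cfg)
    C_hat <- if (use_correlation && settings$lambda < 1) {
      correlation_matrix(positions, stats::cor(M))
    } else NULL
    scores <- vapply(match_sets, function(ms)
      score_one(ps, ms, settings, C_hat), numeric(1))
    flags <- ifelse(vapply(match_sets, length, integer(1)) == 0L,
                    "empty_match_set", "")
    tab <- rank_scores(data.frame(rank = NA_integer_,
                                  candidate = names(match_sets),
                                  direction = "na", score = scores,
                                  n_features = 0L, dof_or_variance = 0,
                                  flags = flags, stringsAsFactors = FALSE))
    ranks[r] <- reference_rank(tab, target_id)
  }
  structure(list(metabolite_id = target_id, ranks = ranks,
                 r90 = r90(ranks)),
            class = "replicate_result")
}

#' 90th-percentile rank (nearest-rank order statistic)
#'
#' @param ranks integer vector of replicate ranks.
#' @return The `ceiling(0.9 * length(ranks))`-th smallest rank.
#' @export
r90 <- function(ranks) {
  stopifnot(length(ranks) >= 1, all(ranks >= 1))
  sort(ranks)[ceiling(0.9 * length(ranks))]
}

#' @export
print.replicate_result <- function(x, ...) {
  cat(sprintf("<replicate_result> %s: %d replicates, r90 = %d (rank 1 in %.0f%%)\n",
              x$metabolite_id, length(x$ranks), x$r90,
              100 * mean(x$ranks == 1)))
  invisible(x)
}

#' Identification performance across a spectral database
#'
#' Runs [run_replicates()] for every metabolite of the database under each
#' supplied configuration, and tabulates the spectrum size, the match-set
#' count `eta` of the lead peak (the bin of height 1), and `r90`. Pearson
#' correlation of `r90` with spectrum size, and Spearman correlation of
#' `r90` with lead-peak `eta`, summarize how spectrum size helps and
#' chemical-shift crowding hurts identification; degenerate cases (zero
#' variance in `r90`) yield `NA` with a flag.
#'
#' @param db a [spectral_db()].
#' @param cfgs a [sim_config()] or list of them (a grid over `beta`,
#'   `n_noise`, `alpha`, ...).
#' @param settings a [scoring_settings()].
#' @param eta_delta neighborhood parameter used for the `eta` crowding
#'   counts (default 0.02).
#' @return An object of class `performance_sweep`: list with `table` (one
#'   row per metabolite x configuration) and `correlations` (per
#'   configuration: `cor_r90_size`, `cor_r90_eta_lead`, the latter Spearman).
#' @export
performance_sweep <- function(db, cfgs, settings = scoring_settings(),
                              eta_delta = 0.02) {
  if (inherits(cfgs, "sim_config")) cfgs <- list(cfgs)
  stopifnot(inherits(db, "spectral_db"), length(cfgs) >= 1)
  positions <- NULL
  rows <- list()
  cors <- list()
  for (ci in seq_along(cfgs)) {
    cfg <- cfgs[[ci]]
    positions <- grid_centers(cfg$bin_width, cfg$range)
    eta_counts <- eta(db, positions, delta = eta_delta, mode = settings$mode)
    res <- lapply(db_ids(db), function(id) {
      sp <- db$spectra[[id]]
      h <- round_to_grid(sp, cfg$bin_width, cfg$range)
      lead_bin <- which.max(h)
      rr <- run_replicates(db, id, cfg, settings)
      data.frame(metabolite_id = id,
                 s_m = sum(h),
                 eta_lead = eta_counts[lead_bin],
                 beta = cfg$beta, N_a = cfg$n_noise, alpha = cfg$alpha,
                 r90 = rr$r90, stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, res)
    tab$config <- ci
    rows[[ci]] <- tab
    cor_size <- if (stats::sd(tab$r90) > 0 && stats::sd(tab$s_m) > 0) {
      stats::cor(tab$r90, tab$s_m)
    } else NA_real_
    cor_eta <- if (stats::sd(tab$r90) > 0 && stats::sd(tab$eta_lead) > 0) {
      stats::cor(tab$r90, tab$eta_lead, method = "spearman")
    } else NA_real_
    cors[[ci]] <- data.frame(config = ci, beta = cfg$beta, N_a = cfg$n_noise,
                             alpha = cfg$alpha, cor_r90_size = cor_size,
                             cor_r90_eta_lead = cor_eta,
                             degenerate = is.na(cor_size) || is.na(cor_eta))
  }
  structure(list(table = do.call(rbind, rows),
                 correlations = do.call(rbind, cors)),
            class = "performance_sweep")
}

#' @export
print.performance_sweep <- function(x, ...) {
  cat(sprintf("<performance_sweep> %d row(s), %d configuration(s)\n",
              nrow(x$table), nrow(x$correlations)))
  print.data.frame(x$correlations, row.names = FALSE)
  invisible(x)
}

#' Write sweep results as TSV
#'
#' @param sweep a [performance_sweep()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sweep <- function(sweep, path) {
  stopifnot(inherits(sweep, "performance_sweep"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("# performance sweep: r90 per metabolite and configuration", con)
  df <- sweep$table[, c("metabolite_id", "s_m", "eta_lead", "beta", "N_a",
                        "alpha", "r90")]
  writeLines(paste(names(df), collapse = "\t"), con)
  writeLines(do.call(paste, c(df, sep = "\t")), con)
  invisible(path)
}

#' Generate a synthetic reference spectral database
#'
#' Emulates the structure of curated NMR reference collections: each
#' metabolite's spectrum consists of 1-6 peak clusters at positions in
#' \[0.5, 9.5\] ppm, each cluster holding 1-4 peaks within +/- 0.02 ppm of
#' its center; heights are renormalized so the tallest peak is 1. A matching
#' multiplet description encloses each cluster with ~0.02 ppm padding and an
#' integer proton count. Deterministic for a given seed.
#'
#' @param n_metabolites number of spectra.
#' @param n_clusters integer range (length 2) for clusters per metabolite.
#' @param peaks_per_cluster integer range for peaks per cluster.
#' @param cluster_spread half-width of a cluster in ppm.
#' @param position_range ppm interval for cluster centers.
#' @param min_gap minimum distance enforced between any two cluster centers
#'   across the whole database (0 = none). Large values yield databases
#'   whose match sets are pairwise disjoint.
#' @param lead_pool optional vector of ppm positions; each metabolite's lead
#'   (tallest) cluster center is drawn from this pool instead of uniformly,
#'   so metabolites share lead peaks and compete (crowded databases).
#' @param seed RNG seed.
#' @return A [spectral_db()] labelled `"synthetic-seed<seed>"`.
#' @export
generate_synthetic_db <- function(n_metabolites, n_clusters = c(1L, 6L),
                                  peaks_per_cluster = c(1L, 4L),
                                  cluster_spread = 0.02,
                                  position_range = c(0.5, 9.5),
                                  min_gap = 0, lead_pool = NULL, seed = 1) {
  stopifnot(n_metabolites >= 1)
  set.seed(seed)
  used_centers <- numeric(0)
  draw_center <- function() {
    for (try in 1:1000) {
      c0 <- stats::runif(1, position_range[1], position_range[2])
      if (min_gap <= 0 || !length(used_centers) ||
          min(abs(c0 - used_centers)) >= min_gap) {
        used_centers <<- c(used_centers, c0)
        return(c0)
      }
    }
    stop("could not place cluster centers with min_gap = ", min_gap,
         call. = FALSE)
  }
  spectra <- lapply(seq_len(n_metabolites), function(m) {
    k <- sample(n_clusters[1]:n_clusters[2], 1)
    centers <- numeric(k)
    # lead cluster first: optionally drawn from a shared pool
    centers[1] <- if (!is.null(lead_pool)) sample(lead_pool, 1) else
      draw_center()
    if (k > 1) for (j in 2:k) centers[j] <- draw_center()
    peaks <- do.call(rbind, lapply(seq_len(k), function(j) {
      np <- sample(peaks_per_cluster[1]:peaks_per_cluster[2], 1)
      pos <- centers[j] + stats::runif(np, -cluster_spread, cluster_spread)
      hts <- stats::runif(np, 0.1, 1)
      # the lead cluster carries the tallest peak
      if (j == 1) hts[which.max(hts)] <- 1
      data.frame(position = pos, height = hts, cluster = j)
    }))
    peaks$height <- peaks$height / max(peaks$height)
    multiplets <- do.call(rbind, lapply(split(peaks, peaks$cluster),
                                        function(cl) {
      data.frame(low = min(cl$position) - 0.02, high = max(cl$position) + 0.02,
                 protons = sample(1:3, 1) * nrow(cl))
    }))
    metabolite_spectrum(id = sprintf("SM%03d", m),
                        name = sprintf("synthetic metabolite %d", m),
                        peaks = peaks[, c("position", "height")],
                        multiplets = multiplets)
  })
  spectral_db(spectra, label = sprintf("synthetic-seed%d", seed))
}
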