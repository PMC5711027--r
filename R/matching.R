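#' Partition feature positions into neighborhoods
#'
#' Two features belong to the same neighborhood if they are connected by a
#' chain of features each at most `2 * delta` ppm apart. For sorted positions
#' this is a single linear sweep: a new block starts whenever the gap to the
#' previous member exceeds `2 * delta`. Gaps exactly equal to `2 * delta`
#' keep the chain connected (closed-interval convention).
#'
#' @param positions sorted numeric vector of ppm positions.
#' @param delta neighborhood parameter in ppm (>= 0).
#' @return A list of integer vectors partitioning `seq_along(positions)`.
#' @export
neighborhoods <- function(positions, delta) {
  stopifnot(delta >= 0)
  n <- length(positions)
  if (n == 0L) return(list())
  if (is.unsorted(positions)) stop("positions must be sorted", call. = FALSE)
  gaps <- diff(positions)
  new_block <- c(TRUE, gaps > 2 * delta + .ppm_tol)
  split(seq_len(n), cumsum(new_block))
}

#' Build the match set of a metabolite against a pseudospectrum
#'
#' The match set F(m) contains, in peak mode, all features within `delta` ppm
#' of any peak of the reference spectrum; in multiplet mode, all features
#' falling in, or within `delta` of, any multiplet range. Distances exactly
#' equal to `delta` are included. The matched features are additionally
#' partitioned into neighborhoods (see [neighborhoods()]) used by the
#' decorrelated scorings.
#'
#' @param spectrum a [metabolite_spectrum()].
#' @param ps a [pseudospectrum()], or a numeric vector of feature positions.
#' @param delta neighborhood parameter in ppm (>= 0). Typical values: 0.03 in
#'   peak mode, 0.01 in multiplet mode.
#' @param mode `"peak"` or `"multiplet"`.
#' @return An object of class `match_set` with fields `metabolite_ids`,
#'   `feature_idx` (sorted indices into the pseudospectrum), `blocks`
#'   (neighborhood partition of `feature_idx`), `positions`, `delta`, `mode`
#'   and `missing_description` (TRUE when the spectrum lacks the requested
#'   description, in which case the match set is empty).
#' @export
build_match_set <- function(spectrum, ps, delta = 0.03,
                            mode = c("peak", "multiplet")) {
  mode <- match.arg(mode)
  stopifnot(inherits(spectrum, "metabolite_spectrum"), delta >= 0)
  positions <- if (inherits(ps, "pseudospectrum")) ps$features$position else
    as.numeric(ps)
  missing_description <- FALSE
  if (mode == "peak") {
    if (nrow(spectrum$peaks) == 0L) {
      missing_description <- TRUE
      idx <- integer(0)
    } else {
      anchors <- spectrum$peaks$position
      dist_min <- Reduce(pmin, lapply(anchors, function(a) abs(positions - a)))
      idx <- which(dist_min <= delta + .ppm_tol)
    }
  } else {
    if (nrow(spectrum$multiplets) == 0L) {
      missing_description <- TRUE
      idx <- integer(0)
    } else {
      lo <- spectrum$multiplets$low - delta
      hi <- spectrum$multiplets$high + delta
      in_any <- Reduce(`|`, lapply(seq_along(lo), function(k)
        positions >= lo[k] - .ppm_tol & positions <= hi[k] + .ppm_tol))
      idx <- which(in_any)
    }
  }
  if (missing_description) {
    warning("spectrum '", spectrum$id, "' has no ", mode,
            " description; match set is empty", call. = FALSE)
  }
  new_match_set(spectrum$id, idx, positions, delta, mode, missing_description)
}

new_match_set <- function(ids, idx, all_positions, delta, mode,
                          missing_description = FALSE) {
  idx <- sort(unique(as.integer(idx)))
  pos <- all_positions[idx]
  blocks <- lapply(neighborhoods(pos, delta), function(b) idx[b])
  structure(
    list(metabolite_ids = ids, feature_idx = idx, positions = pos,
         blocks = unname(blocks), delta = delta, mode = mode,
         n_total_features = length(all_positions),
         all_positions = all_positions,
         missing_description = missing_description),
    class = "match_set"
  )
}

#' @export
print.match_set <- function(x, ...) {
  cat(sprintf("<match_set> %s [%s mode, delta=%g]: %d feature(s) in %d block(s)%s\n",
              paste(x$metabolite_ids, collapse = "+"), x$mode, x$delta,
              length(x$feature_idx), length(x$blocks),
              if (x$missing_description) " (missing description)" else ""))
  invisible(x)
}

#' @export
length.match_set <- function(x) length(x$feature_idx)

#' Union of two match sets (pair match set)
#'
#' For 2-compound scoring, metabolite pairs are scored over the pair match
#' set F(m1, m2) = F(m1) u F(m2). Neighborhood blocks are recomputed on the
#' union, since merging can connect previously separate neighborhoods.
#'
#' @param ms1,ms2 [build_match_set()] results computed against the same
#'   pseudospectrum with identical `delta` and `mode`.
#' @return A `match_set` whose `metabolite_ids` holds both ids.
#' @export
pair_match_set <- function(ms1, ms2) {
  stopifnot(inherits(ms1, "match_set"), inherits(ms2, "match_set"))
  if (ms1$delta != ms2$delta || ms1$mode != ms2$mode ||
      ms1$n_total_features != ms2$n_total_features) {
    stop("match sets were built with different delta/mode/pseudospectrum",
         call. = FALSE)
  }
  ids <- unique(c(ms1$metabolite_ids, ms2$metabolite_ids))
  new_match_set(ids, union(ms1$feature_idx, ms2$feature_idx),
                ms1$all_positions, ms1$delta, ms1$mode,
                ms1$missing_description && ms2$missing_description)
}

#' Per-feature match-set membership counts
#'
#' For every feature of a pseudospectrum, counts the number of metabolites in
#' the database whose match set contains it. Features with high counts sit in
#' crowded chemical-shift regions and face more competition: a genetic-noise
#' association at such a feature boosts many candidates at once.
#'
#' @param db a [spectral_db()].
#' @param ps a [pseudospectrum()] or numeric position vector.
#' @param delta neighborhood parameter (ppm).
#' @param mode `"peak"` or `"multiplet"`.
#' @return Integer vector, one count per feature (eta).
#' @export
eta <- function(db, ps, delta = 0.03, mode = c("peak", "multiplet")) {
  mode <- match.arg(mode)
  stopifnot(inherits(db, "spectral_db"))
  positions <- if (inherits(ps, "pseudospectrum")) ps$features$position else
    as.numeric(ps)
  counts <- integer(length(positions))
  for (sp in db$spectra) {
    ms <- suppressWarnings(build_match_set(sp, positions, delta, mode))
    counts[ms$feature_idx] <- counts[ms$feature_idx] + 1L
  }
  counts
}

#' Dump match sets of a database as a TSV table (debug aid)
#'
#' @inheritParams eta
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_match_sets <- function(db, ps, delta = 0.03,
                             mode = c("peak", "multiplet"), path) {
  mode <- match.arg(mode)
  rows <- list()
  for (sp in db$spectra) {
    ms <- suppressWarnings(build_match_set(sp, ps, delta, mode))
    if (!length(ms$feature_idx)) next
    block_of <- integer(length(ms$feature_idx))
    for (b in seq_along(ms$blocks)) {
      block_of[match(ms$blocks[[b]], ms$feature_idx)] <- b
    }
    rows[[sp$id]] <- data.frame(metabolite_id = sp$id,
                                feature_ppm = ms$positions,
                                block = block_of)
  }
  out <- do.call(rbind, rows)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
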