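#' Rank a score table
#'
#' Ranks candidates by descending score with competition ("1, 1, 3") ranking:
#' ties share the minimal rank, and the next distinct score resumes at its
#' positional rank. Flagged candidates with empty match sets are placed after
#' every scored candidate. Within equal rank, input order is preserved, so
#' ranking is idempotent and stable.
#'
#' @param table a score table data.frame with columns `score` and `flags`
#'   (as produced by [score_database()], ranked or not).
#' @return The table sorted by rank, with the `rank` column filled in.
#' @export
rank_scores <- function(table) {
  stopifnot(is.data.frame(table), all(c("score", "flags") %in% names(table)))
  if (any(!is.finite(table$score))) stop("scores must be finite", call. = FALSE)
  empty <- table$flags %in% c("empty_match_set", "missing_description")
  # sort key: scored candidates first by descending score, then empties;
  # order() is stable, preserving input order within ties
  ord <- order(empty, -table$score)
  out <- table[ord, , drop = FALSE]
  key <- ifelse(empty[ord], -Inf, out$score)
  n <- nrow(out)
  rnk <- integer(n)
  for (i in seq_len(n)) {
    rnk[i] <- if (i > 1L && key[i] == key[i - 1L]) rnk[i - 1L] else i
  }
  out$rank <- rnk
  rownames(out) <- NULL
  out
}

#' Rank of a reference metabolite in a score table
#'
#' For pair candidates, a candidate "contains" the reference if either member
#' matches, and the best (smallest) rank over containing candidates is
#' returned. For directional tables the best rank over both directions is
#' returned unless `direction` is given.
#'
#' @param table a ranked `score_table`.
#' @param reference_id metabolite id to look up.
#' @param direction optionally restrict to `"+"` or `"-"` rows.
#' @return Integer rank (>= 1).
#' @export
reference_rank <- function(table, reference_id, direction = NULL) {
  stopifnot(is.data.frame(table), length(reference_id) == 1L)
  rows <- table
  if (!is.null(direction)) rows <- rows[rows$direction == direction, , drop = FALSE]
  members <- strsplit(rows$candidate, "+", fixed = TRUE)
  hit <- vapply(members, function(m) reference_id %in% m, logical(1))
  if (!any(hit)) {
    stop("reference metabolite '", reference_id, "' not found in score table",
         call. = FALSE)
  }
  min(rows$rank[hit])
}

#' Score a pseudospectrum against a spectral database
#'
#' The main entry point: builds match sets for every candidate implied by the
#' settings variant, computes the match statistic for each, and returns a
#' results object bundling the ranked score table with its inputs. Methods:
#' `print`, `summary`, and `plot` (the results figure: pseudospectrum on top,
#' then the reference spectra of the highest-ranked candidates with their
#' match sets shaded).
#'
#' @param ps a [pseudospectrum()].
#' @param db a [spectral_db()].
#' @param settings a [scoring_settings()].
#' @param C_hat optional [correlation_matrix()], required when
#'   `settings$lambda < 1`.
#' @param top_k number of top candidates kept for the results figure
#'   (default 8; clipped to the table length).
#' @return An object of class `metabomatch` with elements `table`
#'   (ranked `score_table`), `ps`, `db`, `settings`, `top_k`.
#' @examples
#' db <- generate_synthetic_db(5, seed = 1)
#' ps <- pseudospectrum("rs0", data.frame(
#'   position = grid_centers(), beta = rnorm(1000), se = 1))
#' fit <- metabomatch(ps, db)
#' fit
#' head(fit$table)
#' @export
metabomatch <- function(ps, db, settings = scoring_settings(), C_hat = NULL,
                        top_k = 8L) {
  table <- score_database(ps, db, settings, C_hat)
  top_k <- min(as.integer(top_k), nrow(table))
  structure(list(table = table, ps = ps, db = db, settings = settings,
                 C_hat = C_hat, top_k = top_k),
            class = "metabomatch")
}

#' @export
print.metabomatch <- function(x, ...) {
  cat(sprintf("metabomatch run: variant %s against '%s' (%d spectra)\n",
              x$ps$variant_id, x$db$label, length(x$db)))
  cat("settings: ", format_settings(x$settings), "\n", sep = "")
  print(x$table, n = x$top_k)
  invisible(x)
}

#' @export
summary.metabomatch <- function(object, ...) {
  tab <- object$table
  scored <- tab[tab$flags == "", , drop = FALSE]
  structure(list(
    variant_id = object$ps$variant_id,
    db_label = object$db$label,
    settings = object$settings,
    n_candidates = nrow(tab),
    n_empty = sum(tab$flags != ""),
    top = utils::head(tab, object$top_k),
    score_range = if (nrow(scored)) range(scored$score) else c(NA, NA)
  ), class = "summary.metabomatch")
}

#' @export
print.summary.metabomatch <- function(x, ...) {
  cat(sprintf("metabomatch summary: %s vs '%s'\n", x$variant_id, x$db_label))
  cat("settings: ", format_settings(x$settings), "\n", sep = "")
  cat(sprintf("%d candidate(s), %d with empty match sets; scores in [%.3g, %.3g]\n",
              x$n_candidates, x$n_empty, x$score_range[1], x$score_range[2]))
  cat("top candidates:\n")
  print.data.frame(as.data.frame(x$top), row.names = FALSE)
  invisible(x)
}

# blue-grey-red ramp indexed by signed effect size, for the pseudospectrum
effect_colors <- function(beta) {
  pal <- grDevices::colorRampPalette(c("#2166ac", "#999999", "#b2182b"))(101)
  if (all(beta == 0)) return(rep(pal[51], length(beta)))
  scl <- beta / max(abs(beta))
  pal[round((scl + 1) / 2 * 100) + 1]
}

#' Plot a metabomatch results object
#'
#' Draws the results figure: the pseudospectrum (-log10 p against chemical
#' shift, ppm axis right-to-left per NMR convention, features colored by
#' signed effect size) and, below it, one panel per top-ranked candidate
#' showing its reference peaks (height-coded), the match-set neighborhoods
#' shaded, and the candidate's score.
#'
#' @param x a [metabomatch()] object.
#' @param top_k number of candidate panels (default: the object's `top_k`).
#' @param ... ignored.
#' @return `x`, invisibly.
#' @export
plot.metabomatch <- function(x, top_k = x$top_k, ...) {
  tab <- x$table
  top_k <- min(as.integer(top_k), nrow(tab))
  top <- utils::head(tab, top_k)
  ps <- x$ps
  xlim <- rev(range(ps$features$position))  # NMR convention: ppm decreasing
  old <- graphics::par(mfrow = c(top_k + 1L, 1L),
                       mar = c(1.2, 4, 1.2, 1), oma = c(3, 0, 2, 0))
  on.exit(graphics::par(old))
  nlp <- -log10(ps$features$p)
  graphics::plot(ps$features$position, nlp, type = "h", xlim = xlim,
                 col = effect_colors(ps$features$beta),
                 xlab = "", ylab = "-log10 p", xaxt = "n", bty = "l")
  graphics::mtext(sprintf("%s  [%s]", ps$variant_id,
                          format_settings(x$settings)),
                  side = 3, line = 0.5, cex = 0.8)
  hpal <- grDevices::colorRampPalette(c("#c6dbef", "#08306b"))(101)
  for (r in seq_len(top_k)) {
    row <- top[r, ]
    ids <- strsplit(row$candidate, "+", fixed = TRUE)[[1]]
    graphics::plot(NA, xlim = xlim, ylim = c(0, 1.15), xlab = "", ylab = "",
                   yaxt = "n", xaxt = if (r == top_k) "s" else "n", bty = "l")
    for (id in ids) {
      sp <- x$db$spectra[[id]]
      ms <- suppressWarnings(
        build_match_set(sp, ps, x$settings$delta, x$settings$mode))
      for (b in ms$blocks) {
        pos <- ps$features$position[b]
        graphics::rect(min(pos) - x$settings$delta, 0,
                       max(pos) + x$settings$delta, 1.1,
                       col = "#fddbc733", border = NA)
      }
      if (nrow(sp$peaks)) {
        graphics::segments(sp$peaks$position, 0, sp$peaks$position,
                           sp$peaks$height,
                           col = hpal[round(sp$peaks$height * 100) + 1], lwd = 2)
      }
      if (nrow(sp$multiplets)) {
        graphics::segments(sp$multiplets$low, 1.05, sp$multiplets$high, 1.05,
                           col = "#08306b", lwd = 2)
      }
    }
    names <- vapply(ids, function(i) x$db$spectra[[i]]$name, character(1))
    lab <- sprintf("%d. %s  score %.2f%s", row$rank,
                   paste(names, collapse = " + "), row$score,
                   if (row$direction %in% c("+", "-"))
                     paste0("  (", row$direction, ")") else "")
    graphics::mtext(lab, side = 3, line = 0, adj = 0, cex = 0.7)
  }
  graphics::mtext("chemical shift (ppm)", side = 1, line = 1.5, outer = TRUE,
                  cex = 0.8)
  invisible(x)
}

#' Render the results figure to an SVG file
#'
#' @param x a [metabomatch()] object.
#' @param path output path (`.svg`).
#' @param top_k number of candidate panels.
#' @param width,height figure size in inches.
#' @return `path`, invisibly.
#' @export
render_figure <- function(x, path, top_k = x$top_k, width = 8,
                          height = 1.2 * (min(top_k, nrow(x$table)) + 2)) {
  stopifnot(inherits(x, "metabomatch"))
  grDevices::svg(path, width = width, height = height)
  on.exit(grDevices::dev.off())
  plot(x, top_k = top_k)
  invisible(path)
}
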