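#' Construct an association pseudospectrum
#'
#' A pseudospectrum collects, for one genetic variant, the summary statistics
#' of the simple linear regressions between that variant and every binned NMR
#' metabolome feature: effect size `beta`, standard error `se` (> 0) and
#' p-value `p`, indexed by the feature's chemical-shift position (bin center,
#' ppm). Plotted as -log10(p) against ppm it mirrors the NMR spectrum of the
#' metabolite whose concentration the variant modulates.
#'
#' @param variant_id identifier of the variant (e.g. an rs number).
#' @param features `data.frame` with columns `position`, `beta`, `se` and
#'   optionally `p`. Positions must be unique and within \[0, 12\] ppm; `se`
#'   strictly positive. When `p` is absent it is recomputed from `beta / se`
#'   as a two-sided normal tail and the object is flagged (`p_imputed`).
#'
#' @return An object of class `pseudospectrum` with features sorted by
#'   position.
#' @export
pseudospectrum <- function(variant_id, features) {
  stopifnot(is.character(variant_id), length(variant_id) == 1L)
  features <- as.data.frame(features)
  need <- c("position", "beta", "se")
  if (!all(need %in% names(features))) {
    stop("features need columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (nrow(features) == 0L) stop("pseudospectrum must be non-empty", call. = FALSE)
  if (any(features$se <= 0)) stop("standard errors must be > 0", call. = FALSE)
  if (any(features$position < 0 | features$position > 12)) {
    stop("feature positions must lie in [0, 12] ppm", call. = FALSE)
  }
  p_imputed <- FALSE
  if (is.null(features[["p"]]) || all(is.na(features[["p"]]))) {
    # floored at the smallest positive double: scoring works from beta/se,
    # so underflow of the two-sided tail only affects the stored p
    features$p <- pmax(2 * stats::pnorm(-abs(features$beta / features$se)),
                       .Machine$double.xmin)
    p_imputed <- TRUE
  }
  if (any(features$p <= 0 | features$p > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  features <- features[order(features$position),
                       c("position", "beta", "se", "p"), drop = FALSE]
  rownames(features) <- NULL
  if (anyDuplicated(round(features$position / 1e-4))) {
    stop("duplicate feature positions", call. = FALSE)
  }
  structure(list(variant_id = variant_id, features = features,
                 p_imputed = p_imputed),
            class = "pseudospectrum")
}

#' @export
print.pseudospectrum <- function(x, ...) {
  cat(sprintf("<pseudospectrum> %s: %d features over [%.3f, %.3f] ppm%s\n",
              x$variant_id, nrow(x$features), min(x$features$position),
              max(x$features$position),
              if (x$p_imputed) " (p recomputed from beta/se)" else ""))
  invisible(x)
}

#' @export
length.pseudospectrum <- function(x) nrow(x$features)

#' Read a pseudospectrum from TSV
#'
#' Expected format: a comment header line `#variant <id>` followed by a
#' tab-separated table with columns `position_ppm`, `beta`, `se` and
#' optionally `p`. Missing p-values are recomputed from `beta / se`
#' (two-sided normal) and flagged.
#'
#' @param path file path.
#' @return A [pseudospectrum()].
#' @seealso [write_pseudospectrum()]
#' @export
read_pseudospectrum <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  vline <- grep("^#variant\\s+", lines, value = TRUE)
  variant_id <- if (length(vline)) sub("^#variant\\s+", "", vline[1]) else "unknown"
  tab <- utils::read.table(text = lines, header = TRUE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("position_ppm", "beta", "se") %in% names(tab))) {
    stop("malformed pseudospectrum '", path,
         "': expected columns position_ppm, beta, se[, p]", call. = FALSE)
  }
  feats <- data.frame(position = tab$position_ppm, beta = tab$beta, se = tab$se)
  if ("p" %in% names(tab)) feats$p <- tab$p
  pseudospectrum(variant_id, feats)
}

#' Write a pseudospectrum to TSV
#'
#' @param ps a [pseudospectrum()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pseudospectrum <- function(ps, path) {
  stopifnot(inherits(ps, "pseudospectrum"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("#variant %s", ps$variant_id), con)
  writeLines(paste("position_ppm", "beta", "se", "p", sep = "\t"), con)
  num <- function(x) formatC(x, format = "g", digits = 17)
  writeLines(paste(num(ps$features$position), num(ps$features$beta),
                   num(ps$features$se), num(ps$features$p), sep = "\t"), con)
  invisible(path)
}

#' Construct a feature-feature correlation matrix
#'
#' @param positions ppm positions matching a pseudospectrum, in order.
#' @param values square symmetric matrix with unit diagonal and entries in
#'   \[-1, 1\].
#' @return An object of class `correlation_matrix`.
#' @export
correlation_matrix <- function(positions, values) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == ncol(values), length(positions) == nrow(values))
  if (max(abs(values - t(values))) > 1e-8) {
    stop("correlation matrix is not symmetric (tolerance 1e-8)", call. = FALSE)
  }
  if (max(abs(diag(values) - 1)) > 1e-8) {
    stop("correlation matrix diagonal must be 1", call. = FALSE)
  }
  if (any(abs(values) > 1 + 1e-8)) {
    stop("correlation entries must lie in [-1, 1]", call. = FALSE)
  }
  values <- (values + t(values)) / 2
  diag(values) <- 1
  structure(list(positions = as.numeric(positions), values = values),
            class = "correlation_matrix")
}

#' Read a feature correlation matrix aligned to a pseudospectrum
#'
#' Format: first row lists the feature positions (tab-separated), followed by
#' the square matrix, one row per line. The positions must match the
#' pseudospectrum's feature positions (tolerance 1e-6) and in the same order.
#'
#' @param path file path.
#' @param ps the [pseudospectrum()] the matrix belongs to.
#' @return A [correlation_matrix()].
#' @export
read_correlation <- function(path, ps) {
  stopifnot(inherits(ps, "pseudospectrum"))
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  header <- as.numeric(strsplit(lines[1], "\t", fixed = TRUE)[[1]])
  n <- nrow(ps$features)
  if (length(header) != n) {
    stop("correlation matrix dimension (", length(header),
         ") does not match pseudospectrum feature count (", n, ")", call. = FALSE)
  }
  if (max(abs(header - ps$features$position)) > 1e-6) {
    stop("correlation matrix positions do not match pseudospectrum positions",
         call. = FALSE)
  }
  vals <- do.call(rbind, lapply(lines[-1], function(l)
    as.numeric(strsplit(l, "\t", fixed = TRUE)[[1]])))
  if (nrow(vals) != n || ncol(vals) != n) {
    stop("correlation matrix is not ", n, "x", n, call. = FALSE)
  }
  correlation_matrix(header, vals)
}

#' Write a feature correlation matrix
#'
#' @param cm a [correlation_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_correlation <- function(cm, path) {
  stopifnot(inherits(cm, "correlation_matrix"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  num <- function(x) formatC(x, format = "g", digits = 17)
  writeLines(paste(num(cm$positions), collapse = "\t"), con)
  for (i in seq_len(nrow(cm$values))) {
    writeLines(paste(num(cm$values[i, ]), collapse = "\t"), con)
  }
  invisible(path)
}

#' Split a pseudospectrum by effect direction
#'
#' For variants affecting two metabolites with opposite effect directions,
#' scoring is run separately per direction after suppressing the confidently
#' opposite-direction signal. The `+` copy zeroes `beta` for features with
#' `beta < 0` whose association is stronger than the threshold; the `-` copy
#' does the symmetric thing. Standard errors, p-values and positions are left
#' untouched, so the feature count (and hence degrees of freedom downstream)
#' is unchanged.
#'
#' @param ps a [pseudospectrum()].
#' @param p_threshold p-value threshold in (0, 1). By default, zeroing applies
#'   to opposite-direction features *more significant* than the threshold
#'   (`p < p_threshold`), so that only a confidently opposite metabolite
#'   signal — not background noise — is removed; set
#'   `zero_if = "less_significant"` for the complementary reading
#'   (`p > p_threshold`).
#' @param zero_if which opposite-direction features to zero:
#'   `"more_significant"` (default) or `"less_significant"`.
#' @return A list with elements `plus` and `minus`, both [pseudospectrum()]s.
#' @export
split_by_direction <- function(ps, p_threshold = 1e-6,
                               zero_if = c("more_significant", "less_significant")) {
  stopifnot(inherits(ps, "pseudospectrum"),
            p_threshold > 0, p_threshold < 1)
  zero_if <- match.arg(zero_if)
  crosses <- if (zero_if == "more_significant") {
    ps$features$p < p_threshold
  } else {
    ps$features$p > p_threshold
  }
  make <- function(sign_keep, tag) {
    f <- ps$features
    zap <- if (sign_keep > 0) f$beta < 0 & crosses else f$beta > 0 & crosses
    f$beta[zap] <- 0
    out <- ps
    out$variant_id <- paste0(ps$variant_id, tag)
    out$features <- f
    out
  }
  list(plus = make(+1, "(+)"), minus = make(-1, "(-)"))
}
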