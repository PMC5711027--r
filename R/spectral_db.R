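#' @title Reference spectral databases
#' @name spectral_db
#' @description
#' A spectral database is an ordered collection of metabolite reference
#' spectra. Each spectrum carries a peak description (chemical shift in ppm
#' plus relative height, the tallest peak having height 1) and/or a multiplet
#' description (a ppm range plus an integer proton count). Databases are read
#' from and written to a flat TSV format; see [read_spectral_db()].
NULL

# ppm positions are stored at 1e-4 resolution; comparisons use this tolerance
.ppm_tol <- 1e-6

#' Construct a metabolite reference spectrum
#'
#' @param id stable identifier string (unique within a database).
#' @param name display name; defaults to `id`.
#' @param peaks `data.frame` with columns `position` (ppm, in \[0, 12\]) and
#'   `height` (relative intensity in (0, 1\]), or `NULL`.
#' @param multiplets `data.frame` with columns `low`, `high` (ppm range,
#'   `low < high`) and `protons` (non-negative integer), or `NULL`.
#'
#' @details At least one description must be non-empty. Peak heights are
#'   relative to the tallest peak, so the maximum height must equal 1
#'   (tolerance 1e-6). Rows are sorted by `position` (peaks) and `low`
#'   (multiplets) on construction.
#'
#' @return An object of class `metabolite_spectrum`.
#' @export
metabolite_spectrum <- function(id, name = id, peaks = NULL, multiplets = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (is.null(peaks)) {
    peaks <- data.frame(position = numeric(0), height = numeric(0))
  }
  if (is.null(multiplets)) {
    multiplets <- data.frame(low = numeric(0), high = numeric(0),
                             protons = integer(0))
  }
  peaks <- as.data.frame(peaks)[, c("position", "height")]
  multiplets <- as.data.frame(multiplets)[, c("low", "high", "protons")]
  if (nrow(peaks) == 0L && nrow(multiplets) == 0L) {
    stop("spectrum '", id, "': needs at least one peak or multiplet", call. = FALSE)
  }
  if (nrow(peaks) > 0L) {
    if (any(peaks$position < 0 | peaks$position > 12)) {
      stop("spectrum '", id, "': peak position outside [0, 12] ppm", call. = FALSE)
    }
    if (any(peaks$height <= 0 | peaks$height > 1 + .ppm_tol)) {
      stop("spectrum '", id, "': peak height outside (0, 1]", call. = FALSE)
    }
    if (abs(max(peaks$height) - 1) > 1e-6) {
      stop("spectrum '", id, "': maximum peak height must be 1 (relative intensity)",
           call. = FALSE)
    }
    peaks <- peaks[order(peaks$position), , drop = FALSE]
    rownames(peaks) <- NULL
  }
  if (nrow(multiplets) > 0L) {
    if (any(multiplets$low >= multiplets$high)) {
      stop("spectrum '", id, "': multiplet range must satisfy low < high", call. = FALSE)
    }
    if (any(multiplets$protons < 0) ||
        any(abs(multiplets$protons - round(multiplets$protons)) > .ppm_tol)) {
      stop("spectrum '", id, "': proton count must be a non-negative integer",
           call. = FALSE)
    }
    multiplets$protons <- as.integer(round(multiplets$protons))
    multiplets <- multiplets[order(multiplets$low), , drop = FALSE]
    rownames(multiplets) <- NULL
  }
  structure(
    list(id = id, name = name, peaks = peaks, multiplets = multiplets),
    class = "metabolite_spectrum"
  )
}

#' @export
print.metabolite_spectrum <- function(x, ...) {
  cat(sprintf("<metabolite_spectrum> %s (%s): %d peak(s), %d multiplet(s)\n",
              x$id, x$name, nrow(x$peaks), nrow(x$multiplets)))
  invisible(x)
}

#' Construct a spectral database
#'
#' @param spectra list of [metabolite_spectrum()] objects with unique ids.
#' @param label provenance string, e.g. `"umdb"` or `"synthetic-seed42"`.
#'
#' @return An object of class `spectral_db`: a named, ordered collection of
#'   spectra.
#' @export
spectral_db <- function(spectra, label = "unlabeled") {
  stopifnot(is.list(spectra), length(spectra) > 0L)
  ok <- vapply(spectra, inherits, logical(1), "metabolite_spectrum")
  if (!all(ok)) stop("all elements must be metabolite_spectrum objects", call. = FALSE)
  ids <- vapply(spectra, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    stop("duplicate metabolite ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  names(spectra) <- ids
  structure(list(spectra = spectra, label = label), class = "spectral_db")
}

#' @export
print.spectral_db <- function(x, ...) {
  cat(sprintf("<spectral_db> '%s': %d spectra\n", x$label, length(x$spectra)))
  invisible(x)
}

#' @export
length.spectral_db <- function(x) length(x$spectra)

#' @rdname spectral_db
#' @param db a `spectral_db`.
#' @export
db_ids <- function(db) {
  stopifnot(inherits(db, "spectral_db"))
  names(db$spectra)
}

#' Read a spectral database from a flat TSV file
#'
#' The format is tab-separated, UTF-8, with `#` comment lines and a header
#' row `metabolite_id  name  kind  a  b  protons`. For `kind = "peak"`,
#' `a` is the chemical shift (ppm) and `b` the relative height; for
#' `kind = "multiplet"`, `a`/`b` are the low/high ends of the ppm range and
#' `protons` the proton count. One row per peak or multiplet.
#'
#' @param path file path.
#' @param description which description(s) to load: `"both"` (default),
#'   `"peak"` or `"multiplet"`. Spectra missing the requested description are
#'   retained (their match sets will be empty in that mode).
#' @param label provenance label; defaults to the file name.
#'
#' @return A [spectral_db()].
#' @seealso [write_spectral_db()]
#' @export
read_spectral_db <- function(path, description = c("both", "peak", "multiplet"),
                             label = basename(path)) {
  description <- match.arg(description)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                           quote = "", stringsAsFactors = FALSE,
                           colClasses = c(metabolite_id = "character",
                                          name = "character", kind = "character",
                                          a = "numeric", b = "numeric",
                                          protons = "numeric"))
  required <- c("metabolite_id", "name", "kind", "a", "b", "protons")
  if (!all(required %in% names(raw))) {
    stop("malformed spectral db '", path, "': expected columns ",
         paste(required, collapse = ", "), call. = FALSE)
  }
  bad <- which(!raw$kind %in% c("peak", "multiplet"))
  if (length(bad)) {
    stop("malformed row ", bad[1] + 1L, " in '", path, "': unknown kind '",
         raw$kind[bad[1]], "'", call. = FALSE)
  }
  ids <- unique(raw$metabolite_id)
  spectra <- lapply(ids, function(i) {
    rows <- raw[raw$metabolite_id == i, , drop = FALSE]
    peaks <- NULL
    multiplets <- NULL
    if (description %in% c("both", "peak")) {
      pk <- rows[rows$kind == "peak", , drop = FALSE]
      if (nrow(pk)) peaks <- data.frame(position = pk$a, height = pk$b)
    }
    if (description %in% c("both", "multiplet")) {
      mp <- rows[rows$kind == "multiplet", , drop = FALSE]
      if (nrow(mp)) multiplets <- data.frame(low = mp$a, high = mp$b,
                                             protons = mp$protons)
    }
    if (is.null(peaks) && is.null(multiplets)) {
      # requested description absent: keep the spectrum, flagged by whatever
      # description the file does provide, so match sets come out empty
      pk <- rows[rows$kind == "peak", , drop = FALSE]
      mp <- rows[rows$kind == "multiplet", , drop = FALSE]
      if (nrow(pk)) peaks <- data.frame(position = pk$a, height = pk$b)
      if (nrow(mp)) multiplets <- data.frame(low = mp$a, high = mp$b,
                                             protons = mp$protons)
    }
    metabolite_spectrum(id = i, name = rows$name[1], peaks = peaks,
                        multiplets = multiplets)
  })
  spectral_db(spectra, label = label)
}

#' Write a spectral database to the flat TSV format
#'
#' Inverse of [read_spectral_db()]: `read(write(db))` reproduces the database
#' (ids bit-stable, ppm values at full double precision via `format(...,
#' digits = 17)`-equivalent decimal repr).
#'
#' @param db a [spectral_db()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_spectral_db <- function(db, path) {
  stopifnot(inherits(db, "spectral_db"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# spectral database: %s", db$label), con)
  writeLines(paste("metabolite_id", "name", "kind", "a", "b", "protons",
                   sep = "\t"), con)
  num <- function(x) formatC(x, format = "g", digits = 17)
  for (sp in db$spectra) {
    if (nrow(sp$peaks)) {
      writeLines(paste(sp$id, sp$name, "peak", num(sp$peaks$position),
                       num(sp$peaks$height), "0", sep = "\t"), con)
    }
    if (nrow(sp$multiplets)) {
      writeLines(paste(sp$id, sp$name, "multiplet", num(sp$multiplets$low),
                       num(sp$multiplets$high), sp$multiplets$protons,
                       sep = "\t"), con)
    }
  }
  invisible(path)
}

#' Subset a spectral database by metabolite id
#'
#' Biofluid-specific subsets of a full database (e.g. the urine subset of a
#' large reference collection) are first-class databases: the order of the
#' parent is preserved and the label records the subsetting.
#'
#' @param db a [spectral_db()].
#' @param ids character vector of ids to keep; must all be present and
#'   non-empty.
#' @return A [spectral_db()] with the selected spectra in parent order.
#' @export
subset_db <- function(db, ids) {
  stopifnot(inherits(db, "spectral_db"))
  if (length(ids) == 0L) stop("empty subset: a spectral database must be non-empty",
                              call. = FALSE)
  missing <- setdiff(ids, db_ids(db))
  if (length(missing)) {
    stop("unknown metabolite id(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  keep <- db_ids(db) %in% ids
  spectral_db(db$spectra[keep],
              label = sprintf("%s[subset:%d]", db$label, sum(keep)))
}

.bin_index <- function(position, lo, bin_width) {
  # half-open bins [lo + k w, lo + (k+1) w); a position exactly on a boundary
  # belongs to the upper bin, hence the small positive nudge before floor()
  as.integer(floor((position - lo) / bin_width + 1e-9)) + 1L
}

#' Round a reference spectrum to a uniform chemical-shift binning
#'
#' Produces the binned height vector `h` with `h[j]` the height of the peak in
#' bin `j` and 0 where the spectrum has no peak. Bins are half-open
#' `[lo + k w, lo + (k+1) w)`; a peak exactly on a boundary goes to the upper
#' bin, and multiple peaks landing in one bin have their heights summed, which
#' conserves the total height.
#'
#' @param spectrum a [metabolite_spectrum()] with a peak description.
#' @param bin_width bin width in ppm (> 0).
#' @param range numeric length-2, the binned chemical-shift range in ppm
#'   (default `c(0, 10)`); all peaks must fall inside.
#' @return Numeric vector of length `ceiling((hi - lo) / bin_width)`.
#' @export
round_to_grid <- function(spectrum, bin_width = 0.01, range = c(0, 10)) {
  stopifnot(inherits(spectrum, "metabolite_spectrum"), bin_width > 0,
            length(range) == 2L, range[1] < range[2])
  if (nrow(spectrum$peaks) == 0L) {
    stop("spectrum '", spectrum$id, "' has no peak description", call. = FALSE)
  }
  pos <- spectrum$peaks$position
  if (any(pos < range[1] - .ppm_tol | pos >= range[2] + .ppm_tol)) {
    stop("spectrum '", spectrum$id, "': peak outside binning range [",
         range[1], ", ", range[2], ")", call. = FALSE)
  }
  n_bins <- as.integer(ceiling((range[2] - range[1]) / bin_width - 1e-9))
  idx <- .bin_index(pos, range[1], bin_width)
  idx <- pmin(idx, n_bins)
  h <- numeric(n_bins)
  for (k in seq_along(idx)) h[idx[k]] <- h[idx[k]] + spectrum$peaks$height[k]
  h
}

#' Size of a reference spectrum on a binning grid
#'
#' The size `s` of a spectrum is the sum of its binned peak heights,
#' `s = sum_j h[j]`, computed after rounding to the grid. Because the tallest
#' peak has height 1, `s >= 1` whenever the spectrum has peaks.
#'
#' @inheritParams round_to_grid
#' @return Numeric scalar.
#' @export
spectrum_size <- function(spectrum, bin_width = 0.01, range = c(0, 10)) {
  sum(round_to_grid(spectrum, bin_width = bin_width, range = range))
}

#' Bin centers of a uniform chemical-shift grid
#'
#' @inheritParams round_to_grid
#' @return Numeric vector of bin-center positions (ppm).
#' @export
grid_centers <- function(bin_width = 0.01, range = c(0, 10)) {
  n_bins <- as.integer(ceiling((range[2] - range[1]) / bin_width - 1e-9))
  range[1] + (seq_len(n_bins) - 0.5) * bin_width
}
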