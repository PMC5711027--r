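# fixture builders shared across test files; everything is generated in code

# pseudospectrum on an explicit position grid with unit standard errors
make_ps <- function(positions, beta, se = 1, variant_id = "rs-test") {
  pseudospectrum(variant_id,
                 data.frame(position = positions, beta = beta, se = se))
}

# pseudospectrum on the default 0.01 ppm bin grid with iid N(0,1) beta/se
noise_ps <- function(seed = 1, variant_id = "rs-noise") {
  set.seed(seed)
  pos <- grid_centers()
  make_ps(pos, stats::rnorm(length(pos)), variant_id = variant_id)
}

# two metabolites with well-separated spectra, peak and multiplet descriptions
tiny_db <- function() {
  m1 <- metabolite_spectrum(
    "ala", "alanine-like",
    peaks = data.frame(position = c(1.47, 1.49, 3.78), height = c(1, 0.9, 0.3)),
    multiplets = data.frame(low = c(1.45, 3.76), high = c(1.51, 3.80),
                            protons = c(3L, 1L)))
  m2 <- metabolite_spectrum(
    "cit", "citrate-like",
    peaks = data.frame(position = c(2.54, 2.66), height = c(1, 0.95)),
    multiplets = data.frame(low = 2.52, high = 2.68, protons = 2L))
  spectral_db(list(m1, m2), label = "tiny")
}

# brute-force neighborhood partition: connected components of the graph
# joining features at most 2*delta apart (independent of the sweep code)
brute_blocks <- function(positions, delta) {
  n <- length(positions)
  if (n == 0L) return(list())
  adj <- abs(outer(positions, positions, "-")) <= 2 * delta + 1e-6
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      nb <- which(adj[i, ])
      new <- min(comp[nb])
      if (new < comp[i]) { comp[nb] <- new; changed <- TRUE }
      else if (any(comp[nb] > comp[i])) { comp[nb] <- comp[i]; changed <- TRUE }
    }
    if (!changed) break
  }
  unname(split(seq_len(n), comp))
}
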