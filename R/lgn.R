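#' Generate a model LGN population with a banded ON/OFF layout
#'
#' Places `n_cells` center-surround-like linear-nonlinear-Poisson (LNP) cells
#' on the stimulus field. Receptive-field centers are arranged along parallel
#' elongated bands of alternating sign, so that the sign-weighted population
#' receptive field shows the ON and OFF subregions of a simple cell -- the
#' geometry a thalamorecipient V1 simple cell pools over.
#'
#' @param n_cells Number of cells, 1..50.
#' @param n_bands Number of parallel ON/OFF bands (alternating sign). Ignored
#'   when `n_cells == 1`.
#' @param field_deg Width of the square stimulus field in degrees.
#' @param rf_width_deg Gaussian SD of the RF center mechanism, degrees.
#' @param baseline_range_hz Range the per-cell baseline firing rate is drawn
#'   from, Hz. Together with `gain_hz` this keeps realized rates in the 2-24 Hz
#'   range typical of visually driven relay cells.
#' @param gain_hz Firing-rate gain, Hz per unit filtered contrast.
#' @param refractory_ms Absolute refractory period, ms.
#' @param seed Optional integer seed.
#'
#' @return A tibble with one row per cell: `cell_id`, `x_deg`, `y_deg`,
#'   `rf_width_deg`, `sign` (+1 ON / -1 OFF), `baseline_rate_hz`, `gain_hz`,
#'   `refractory_ms`. The biphasic frame-lag temporal kernel (transient
#'   excitatory lobe peaking ~3 frames back, delayed suppressive lobe) is
#'   attached as attribute `temporal_kernel`.
#' @export
lgn_population <- function(n_cells = 50, n_bands = 3, field_deg = 4,
                           rf_width_deg = 0.5,
                           baseline_range_hz = c(2, 6), gain_hz = 700,
                           refractory_ms = 1, seed = NULL) {
  if (n_cells < 1 || n_cells > 50) abort("`n_cells` must be between 1 and 50.")
  seed_if(seed)
  if (n_cells == 1L) {
    band <- 1L
    x <- field_deg / 2
    y <- field_deg / 2
    sign <- 1
  } else {
    band <- rep(seq_len(n_bands), length.out = n_cells)
    # bands are horizontal rows: y fixed per band, x spread along the band
    band_y <- field_deg * (seq_len(n_bands) - 0.5) / n_bands
    y <- band_y[band] + rnorm(n_cells, 0, field_deg / (8 * n_bands))
    x <- runif(n_cells, 0.15 * field_deg, 0.85 * field_deg)
    sign <- ifelse(band %% 2 == 1, 1, -1)
  }
  cells <- tibble::tibble(
    cell_id = seq_len(n_cells),
    x_deg = x,
    y_deg = pmin(pmax(y, 0), field_deg),
    rf_width_deg = rf_width_deg * exp(rnorm(n_cells, 0, 0.1)),
    sign = sign,
    baseline_rate_hz = runif(n_cells, baseline_range_hz[1], baseline_range_hz[2]),
    gain_hz = gain_hz,
    refractory_ms = refractory_ms
  )
  # biphasic (transient) frame-lag kernel: relay cells respond briskly to
  # contrast change, with a delayed suppressive lobe
  lag <- seq(0, 11) + 0.5
  k <- stats::dgamma(lag, shape = 4, scale = 1) -
    0.5 * stats::dgamma(lag, shape = 8, scale = 1)
  attr(cells, "temporal_kernel") <- k / sum(pmax(k, 0))
  attr(cells, "field_deg") <- field_deg
  cells
}

# pixel-weight matrix (n_px^2 x n_cells): sign-carrying Gaussian RF, L1-normalized
rf_weights <- function(cells, n_px, field_deg) {
  px <- field_deg * (seq_len(n_px) - 0.5) / n_px
  grid <- expand.grid(y = px, x = px) # row index varies fastest = y
  w <- vapply(seq_len(nrow(cells)), function(i) {
    g <- exp(-((grid$x - cells$x_deg[i])^2 + (grid$y - cells$y_deg[i])^2) /
               (2 * cells$rf_width_deg[i]^2))
    cells$sign[i] * g / sum(g)
  }, numeric(n_px * n_px))
  matrix(w, nrow = n_px * n_px)
}

#' Sign-weighted population receptive field of an LGN population
#'
#' @param cells A population from [lgn_population()].
#' @param n_px Pixels per side of the evaluation grid.
#' @return An `n_px` x `n_px` matrix (rows = y) of summed signed Gaussian RFs.
#' @export
population_rf <- function(cells, n_px = 16) {
  field_deg <- attr(cells, "field_deg") %||% 4
  w <- rf_weights(cells, n_px, field_deg)
  matrix(rowSums(w), n_px, n_px)
}

#' Simulate stimulus-driven LGN spike trains (LNP with refractoriness)
#'
#' Each cell's instantaneous rate is its baseline plus `gain_hz` times the
#' stimulus contrast filtered through its spatial RF and a causal temporal
#' kernel over recent frames; negative rates are clipped at zero. Spikes are
#' drawn as an inhomogeneous Bernoulli process on `dt_ms` bins and thinned to
#' an absolute refractory period.
#'
#' @param stim A [wn_stimulus()], or `NULL` for a zero-contrast (baseline-rate)
#'   simulation of length `duration_s`.
#' @param cells Population tibble from [lgn_population()].
#' @param duration_s Simulated duration; defaults to the stimulus duration.
#' @param dt_ms Simulation bin for the point process, ms.
#' @param seed Optional integer seed.
#'
#' @return A tibble `cell_id`, `spike_time_s`, sorted within cell. Realized
#'   per-cell rates are attached as attribute `rates_hz`.
#' @export
simulate_lgn_spikes <- function(stim, cells, duration_s = NULL, dt_ms = 1,
                                seed = NULL) {
  seed_if(seed)
  if (is.null(duration_s)) {
    if (is.null(stim)) abort("`duration_s` is required when `stim` is NULL.")
    duration_s <- stim$duration_s
  }
  dt <- dt_ms / 1000
  n_bins <- floor(duration_s / dt)
  t_bins <- (seq_len(n_bins) - 1) * dt
  n_cells <- nrow(cells)

  if (is.null(stim)) {
    drive <- matrix(0, n_bins, n_cells)
  } else {
    field_deg <- attr(cells, "field_deg") %||% 4
    w <- rf_weights(cells, stim$n_px, field_deg)
    fmat <- matrix(stim$frames, nrow = dim(stim$frames)[1]) # frames x px^2
    raw <- fmat %*% w                                       # frames x cells
    tk <- attr(cells, "temporal_kernel") %||% 1
    filt <- apply(raw, 2, function(col) {
      stats::filter(col, tk, method = "convolution", sides = 1)
    })
    filt[is.na(filt)] <- 0
    fi <- frame_index_at(stim, t_bins)
    drive <- matrix(0, n_bins, n_cells)
    ok <- !is.na(fi)
    drive[ok, ] <- filt[fi[ok], , drop = FALSE]
  }

  rate <- sweep(drive, 2, cells$gain_hz, `*`)
  rate <- sweep(rate, 2, cells$baseline_rate_hz, `+`)
  rate[rate < 0] <- 0

  p <- pmin(rate * dt, 0.95)
  fire <- matrix(runif(length(p)) < p, n_bins, n_cells)
  out <- purrr::map_dfr(seq_len(n_cells), function(i) {
    idx <- which(fire[, i])
    if (!length(idx)) {
      return(tibble::tibble(cell_id = integer(), spike_time_s = numeric()))
    }
    times <- sort(t_bins[idx] + runif(length(idx), 0, dt))
    times <- enforce_refractory(times, cells$refractory_ms[i] / 1000)
    tibble::tibble(cell_id = cells$cell_id[i], spike_time_s = times)
  })
  rates <- out %>%
    dplyr::count(.data$cell_id) %>%
    dplyr::mutate(rate_hz = .data$n / duration_s)
  attr(out, "rates_hz") <- rates
  attr(out, "duration_s") <- duration_s
  out
}

# drop spikes closer than ref_s to the previous kept spike
enforce_refractory <- function(times, ref_s) {
  if (length(times) < 2L || ref_s <= 0) return(times)
  keep <- logical(length(times))
  last <- -Inf
  for (i in seq_along(times)) {
    if (times[i] - last >= ref_s) {
      keep[i] <- TRUE
      last <- times[i]
    }
  }
  times[keep]
}
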