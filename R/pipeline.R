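#' Run the full synthetic-to-statistics pipeline
#'
#' Drives every stage from one configuration: generate a synthetic cohort of
#' connected pairs (`synth`), fit jitter-corrected STAs and classify
#' connections (`sta`), run the single-spike EPSP detector (`detect`),
#' compute per-pair and population statistics including short-term
#' plasticity (`stats`), and compare reliable vs unreliable synapses in the
#' LIF model (`lif`). Stage dependencies are enforced (e.g. `detect` needs
#' `sta`); any stage failure halts the run with a stage-scoped error. A
#' manifest records seeds, stage order and content hashes so a rerun with
#' the same configuration reproduces identical summaries.
#'
#' @param config A [run_config()] (or path to a YAML one).
#' @return A list of class `pipeline_result` with elements `pairs`
#'   (per-pair tibble of STA verdicts), `summaries`, `stsp`, `correlations`,
#'   `lif` (trial tibble), and `manifest`.
#' @export
run_pipeline <- function(config = run_config()) {
  if (is.character(config)) config <- read_run_config(config)
  stages <- config$stages
  known <- c("synth", "sta", "detect", "stats", "lif")
  if (!all(stages %in% known)) {
    abort(sprintf("unknown stage(s): %s",
                  paste(setdiff(stages, known), collapse = ", ")))
  }
  needs <- list(sta = "synth", detect = "sta", stats = "detect",
                lif = character())
  for (s in stages) {
    missing <- setdiff(needs[[s]] %||% character(), stages)
    if (length(missing)) {
      abort(sprintf("stage '%s' requires stage(s): %s", s,
                    paste(missing, collapse = ", ")))
    }
  }
  out <- list()
  manifest <- list()
  add_manifest <- function(stage, seed, obj) {
    manifest[[length(manifest) + 1L]] <<- tibble::tibble(
      stage = stage, seed = seed, hash = rlang::hash(obj)
    )
  }
  stage_try <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
            parent = e)
    })
  }

  recs <- NULL
  if ("synth" %in% stages) {
    recs <- stage_try("synth", {
      cohort <- synapse_cohort(config$n_synapses, seed = config$seed)
      duration <- config$n_spikes_target / config$lgn_rate_hz
      purrr::map(seq_len(config$n_synapses), function(i) {
        set.seed(config$seed + 100 + i)
        st <- tibble::tibble(
          cell_id = 1L,
          spike_time_s = sort(runif(
            stats::rpois(1, config$n_spikes_target), 0.05, duration - 0.05
          ))
        )
        synthesize_recording(st, cohort[i, ], duration_s = duration,
                             seed = config$seed + 200 + i)
      })
    })
    add_manifest("synth", config$seed, purrr::map(recs, "truth"))
  }

  fits <- NULL
  if ("sta" %in% stages) {
    fits <- stage_try("sta", purrr::imap(recs, function(r, i) {
      sta_connection(extract_pair(r, 1L), jitter_ms = config$jitter_ms,
                     n_boot = config$n_boot, seed = config$seed + 300 + i)
    }))
    out$pairs <- purrr::map_dfr(fits, glance) %>%
      dplyr::mutate(pair_id = dplyr::row_number())
    add_manifest("sta", config$seed, out$pairs)
  }

  detections <- NULL
  if ("detect" %in% stages) {
    detections <- stage_try("detect", purrr::imap(fits, function(f, i) {
      if (!isTRUE(f$connected)) return(NULL)
      detect_epsps(extract_pair(recs[[i]], 1L), fit = f,
                   jitter_ms = config$jitter_ms, seed = config$seed + 400 + i)
    }))
    add_manifest("detect", config$seed,
                 purrr::map(detections, ~ if (!is.null(.x)) .x$label))
  }

  if ("stats" %in% stages) {
    stage_try("stats", {
      keep <- !purrr::map_lgl(detections, is.null)
      out$summaries <- purrr::imap_dfr(detections[keep], function(d, i) {
        summarize_pair(d, pair_id = i)
      })
      out$stsp <- purrr::imap_dfr(detections[keep], function(d, i) {
        dplyr::mutate(stsp_analysis(d, isi_split_ms = config$isi_split_ms),
                      pair_id = i, .before = 1)
      })
      out$correlations <- if (nrow(out$summaries) >= 3) {
        suppressWarnings(population_correlations(out$summaries))
      } else NULL
    })
    add_manifest("stats", config$seed, out$summaries)
  }

  if ("lif" %in% stages) {
    out$lif <- stage_try("lif", {
      set.seed(config$seed + 500)
      stim <- wn_stimulus(
        n_blocks = max(1L, round((config$lif_duration_s + 1) / 5)),
        seed = config$seed + 500
      )
      cells <- lgn_population(config$lif_n_inputs, seed = config$seed + 501)
      trains <- simulate_lgn_spikes(stim, cells, seed = config$seed + 502)
      specs <- assign_synapses(config$lif_n_inputs, seed = config$seed + 503)
      params <- lif_params(duration_s = stim$duration_s)
      compare_reliability(trains, specs, params, n_trials = config$lif_trials,
                          seed = config$seed + 504)
    })
    add_manifest("lif", config$seed, out$lif)
  }

  out$manifest <- dplyr::bind_rows(manifest) %>%
    dplyr::mutate(package_version = as.character(utils::packageVersion("tcsynapse")))
  structure(out, class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat(sprintf("  stages run: %s\n", paste(x$manifest$stage, collapse = " -> ")))
  if (!is.null(x$pairs)) {
    cat(sprintf("  connected pairs: %d / %d\n", sum(x$pairs$connected),
                nrow(x$pairs)))
  }
  if (!is.null(x$summaries) && nrow(x$summaries)) {
    cat(sprintf("  mean %%undetectable: %.1f; mean CV (all): %.2f\n",
                mean(x$summaries$pct_undetectable), mean(x$summaries$cv_all)))
  }
  if (!is.null(x$lif)) {
    r <- x$lif %>%
      dplyr::group_by(.data$mode) %>%
      dplyr::summarise(rate = mean(.data$rate_hz), .groups = "drop")
    cat(sprintf("  LIF rates: %s\n",
                paste(sprintf("%s %.2f Hz", r$mode, r$rate), collapse = ", ")))
  }
  invisible(x)
}
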