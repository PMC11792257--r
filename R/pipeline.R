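#' Analysis configuration for the per-subject pipeline
#'
#' Collects every tunable of the end-to-end analysis with the conventional
#' defaults: HP validity range 300--2000 ms, 256-beat segments, univariate
#' AR orders 8--14, bivariate orders 5--14, LF/HF bands, 1025-point
#' frequency grid, 100 IAAFT surrogate pairs with 100 iterations and the
#' 95th-percentile rejection rule, and the cardiorespiratory /
#' cardiovascular latency conventions (RESP and SAP act on HP at lag 0, HP
#' acts back at lag 1).
#'
#' @param ... Named overrides of the defaults listed above.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    hp_range = c(300, 2000),
    segment_length = 256L,
    order_range_uni = c(8L, 14L),
    order_range_bar = c(5L, 14L),
    bands = lf_hf_bands(),
    n_freq = 1025L,
    n_pairs = 100L,
    n_iter = 100L,
    percentile = 95,
    latency_resp_hp = c(0L, 1L),
    latency_sap_hp = c(0L, 1L),
    refit_order = TRUE,
    run_surrogates = TRUE,
    detector = list(threshold_factor = 0.4, refractory = 0.25)
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown pipeline_config fields: ",
                            paste(unknown, collapse = ", "), call. = FALSE)
  cfg[names(dots)] <- dots
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full per-subject analysis
#'
#' Executes every stage on one recording: beat extraction (when the input is
#' a raw recording), out-of-range repair, random 256-beat segment selection,
#' univariate time- and frequency-domain markers, the two closed-loop pair
#' analyses (HP-RESP read in the HF band, HP-SAP in the LF band) and,
#' optionally, the six surrogate uncoupling tests. A failing stage is
#' recorded per marker without aborting the remaining markers.
#'
#' @param input A [beat_series] or `raw_recording`.
#' @param config A [pipeline_config()].
#' @param subject_id,group,condition Labels carried into the marker set.
#' @param seed Integer seed driving segment selection and surrogate
#'   generation; the whole marker set is a deterministic function of
#'   `(input, config, seed)`.
#' @return Object of class `marker_set`: list with `subject_id`, `group`,
#'   `condition`, `segment_start`, `seeds`, `bar_orders`, numeric `markers`
#'   (mu_hp, var_hp, hf_hp, mu_sap, var_sap, lf_sap, f_resp_bpm,
#'   k2_resp_hp_hf, ck2_resp_to_hp_hf, ck2_hp_to_resp_hf, k2_sap_hp_lf,
#'   ck2_sap_to_hp_lf, ck2_hp_to_sap_lf), logical `verdicts` (sig_*) and a
#'   character list `errors` naming any failed stage.
#' @export
#' @examples
#' bs <- simulate_subject(sim_config("HEALTHY_REST", seed = 5))
#' ms <- run_subject(bs, pipeline_config(run_surrogates = FALSE),
#'                   subject_id = "S05", group = "HEALTHY", condition = "REST")
#' ms$markers
run_subject <- function(input, config = pipeline_config(), subject_id = "S1",
                        group = "", condition = "", seed = 1L) {
  stopifnot(inherits(config, "pipeline_config"))
  errors <- list()
  note <- function(stage, e) errors[[stage]] <<- conditionMessage(e)

  marker_names <- c("mu_hp", "var_hp", "hf_hp", "mu_sap", "var_sap", "lf_sap",
                    "f_resp_bpm", "k2_resp_hp_hf", "ck2_resp_to_hp_hf",
                    "ck2_hp_to_resp_hf", "k2_sap_hp_lf", "ck2_sap_to_hp_lf",
                    "ck2_hp_to_sap_lf")
  verdict_names <- c("sig_k2_resp_hp_hf", "sig_ck2_resp_to_hp_hf",
                     "sig_ck2_hp_to_resp_hf", "sig_k2_sap_hp_lf",
                     "sig_ck2_sap_to_hp_lf", "sig_ck2_hp_to_sap_lf")
  markers <- stats::setNames(rep(NA_real_, length(marker_names)), marker_names)
  verdicts <- stats::setNames(rep(NA, length(verdict_names)), verdict_names)
  bar_orders <- c(resp_hp = NA_integer_, sap_hp = NA_integer_)
  segment_start <- NA_integer_

  series <- tryCatch({
    if (inherits(input, "raw_recording")) {
      pk <- detect_r_peaks(input$ecg, input$fs,
                           threshold_factor = config$detector$threshold_factor,
                           refractory = config$detector$refractory)
      build_beat_series(pk, input$ap, input$resp, input$fs)
    } else if (inherits(input, "beat_series")) {
      input
    } else {
      stop("input must be a beat_series or raw_recording", call. = FALSE)
    }
  }, error = function(e) { note("extraction", e); NULL })

  segment <- NULL
  if (!is.null(series)) {
    segment <- tryCatch({
      rep_series <- repair_series(series, config$hp_range)
      seg <- select_segment(rep_series, config$segment_length,
                            seed = derive_seed(seed, 1L))
      segment_start <- attr(seg, "segment_start")
      seg
    }, error = function(e) { note("segment", e); NULL })
  }

  if (!is.null(segment)) {
    hp <- segment$hp; sap <- segment$sap; resp <- segment$resp
    mean_hp_s <- mean(hp) / 1000

    tryCatch({
      td_hp <- time_domain_markers(hp)
      td_sap <- time_domain_markers(sap)
      markers["mu_hp"] <- td_hp$mean;  markers["var_hp"] <- td_hp$variance
      markers["mu_sap"] <- td_sap$mean; markers["var_sap"] <- td_sap$variance
    }, error = function(e) note("time_domain", e))

    tryCatch({
      comp_hp <- decompose_spectrum(fit_ar(hp, config$order_range_uni, mean_hp_s))
      markers["hf_hp"] <- band_power(comp_hp, config$bands$hf)
    }, error = function(e) note("spectrum_hp", e))
    tryCatch({
      comp_sap <- decompose_spectrum(fit_ar(sap, config$order_range_uni, mean_hp_s))
      markers["lf_sap"] <- band_power(comp_sap, config$bands$lf)
    }, error = function(e) note("spectrum_sap", e))
    tryCatch({
      comp_resp <- decompose_spectrum(fit_ar(resp, config$order_range_uni, mean_hp_s))
      markers["f_resp_bpm"] <- resp_frequency(comp_resp, config$bands$hf)
    }, error = function(e) note("spectrum_resp", e))

    pair <- function(xs, ys, latency, lab) {
      fit <- ck2(xs, ys, mean_hp_s = mean_hp_s,
                 order_range = config$order_range_bar, latency = latency,
                 n_freq = config$n_freq, bands = config$bands, labels = lab)
      if (!fit$stable) stop("unstable BAR fit", call. = FALSE)
      fit
    }
    fit_rh <- tryCatch(pair(resp, hp, config$latency_resp_hp, c("RESP", "HP")),
                       error = function(e) { note("pair_resp_hp", e); NULL })
    if (!is.null(fit_rh)) {
      bar_orders["resp_hp"] <- fit_rh$model$order
      markers["k2_resp_hp_hf"] <- fit_rh$markers["k2_hf"]
      markers["ck2_resp_to_hp_hf"] <- fit_rh$markers["ck2_x_to_y_hf"]
      markers["ck2_hp_to_resp_hf"] <- fit_rh$markers["ck2_y_to_x_hf"]
    }
    fit_sh <- tryCatch(pair(sap, hp, config$latency_sap_hp, c("SAP", "HP")),
                       error = function(e) { note("pair_sap_hp", e); NULL })
    if (!is.null(fit_sh)) {
      bar_orders["sap_hp"] <- fit_sh$model$order
      markers["k2_sap_hp_lf"] <- fit_sh$markers["k2_lf"]
      markers["ck2_sap_to_hp_lf"] <- fit_sh$markers["ck2_x_to_y_lf"]
      markers["ck2_hp_to_sap_lf"] <- fit_sh$markers["ck2_y_to_x_lf"]
    }

    if (isTRUE(config$run_surrogates)) {
      surro <- function(xs, ys, type, direction, band, latency, vseed) {
        tryCatch({
          sp <- marker_spec(type, direction, band, mean_hp_s = mean_hp_s,
                            order_range = config$order_range_bar,
                            latency = latency, n_freq = config$n_freq,
                            bands = config$bands)
          uncoupling_test(xs, ys, sp, n_pairs = config$n_pairs,
                          percentile = config$percentile,
                          master_seed = derive_seed(seed, vseed),
                          n_iter = config$n_iter,
                          refit_order = config$refit_order)$reject
        }, error = function(e) { note(paste0("surrogate_", vseed), e); NA })
      }
      lrh <- config$latency_resp_hp; lsh <- config$latency_sap_hp
      verdicts["sig_k2_resp_hp_hf"] <- surro(resp, hp, "k2", "x_to_y", "hf", lrh, 11L)
      verdicts["sig_ck2_resp_to_hp_hf"] <- surro(resp, hp, "ck2", "x_to_y", "hf", lrh, 12L)
      verdicts["sig_ck2_hp_to_resp_hf"] <- surro(resp, hp, "ck2", "y_to_x", "hf", lrh, 13L)
      verdicts["sig_k2_sap_hp_lf"] <- surro(sap, hp, "k2", "x_to_y", "lf", lsh, 14L)
      verdicts["sig_ck2_sap_to_hp_lf"] <- surro(sap, hp, "ck2", "x_to_y", "lf", lsh, 15L)
      verdicts["sig_ck2_hp_to_sap_lf"] <- surro(sap, hp, "ck2", "y_to_x", "lf", lsh, 16L)
    }
  }

  structure(list(subject_id = subject_id, group = group, condition = condition,
                 segment_start = segment_start, seed = seed,
                 bar_orders = bar_orders, markers = markers,
                 verdicts = verdicts, errors = errors),
            class = "marker_set")
}

#' @export
print.marker_set <- function(x, ...) {
  cat(sprintf("Marker set %s (%s, %s): %d/%d markers, %d/%d verdicts\n",
              x$subject_id, x$group, x$condition,
              sum(!is.na(x$markers)), length(x$markers),
              sum(!is.na(x$verdicts)), length(x$verdicts)))
  if (length(x$errors)) {
    cat("  failed stages:", paste(names(x$errors), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
as.data.frame.marker_set <- function(x, ...) {
  cbind(data.frame(subject_id = x$subject_id, group = x$group,
                   condition = x$condition, segment_start = x$segment_start,
                   seed = x$seed,
                   bar_order_resp_hp = x$bar_orders[["resp_hp"]],
                   bar_order_sap_hp = x$bar_orders[["sap_hp"]]),
        as.data.frame(as.list(x$markers)),
        as.data.frame(as.list(x$verdicts)))
}

#' Aggregate per-subject marker sets into a cohort table
#'
#' For every group x condition cell: mean and standard deviation of each
#' continuous marker, and the percentage of subjects rejecting the
#' uncoupling null for each coupling marker.
#'
#' @param marker_sets List of [run_subject()] results, or the data frame
#'   obtained by row-binding their `as.data.frame()` forms.
#' @return Data frame with one row per group x condition, columns
#'   `<marker>_mean`, `<marker>_sd` and `pct_<verdict>`.
#' @export
aggregate_cohort <- function(marker_sets) {
  if (is.data.frame(marker_sets)) {
    d <- marker_sets
  } else {
    if (length(marker_sets) == 0L) stop("need at least one marker set", call. = FALSE)
    d <- do.call(rbind, lapply(marker_sets, as.data.frame))
  }
  if (any(is.na(d$condition) | d$condition == "")) {
    bad <- d$subject_id[is.na(d$condition) | d$condition == ""]
    stop("missing condition labels for: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  num_cols <- setdiff(names(d)[vapply(d, is.numeric, logical(1))],
                      c("segment_start", "seed"))
  verdict_cols <- names(d)[startsWith(names(d), "sig_")]
  num_cols <- setdiff(num_cols, verdict_cols)
  cells <- unique(d[, c("group", "condition")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sub <- d[d$group == cells$group[i] & d$condition == cells$condition[i], ]
    out <- data.frame(group = cells$group[i], condition = cells$condition[i],
                      n = nrow(sub))
    for (cl in num_cols) {
      v <- sub[[cl]]
      out[[paste0(cl, "_mean")]] <- mean(v, na.rm = TRUE)
      out[[paste0(cl, "_sd")]] <- if (sum(!is.na(v)) > 1) stats::sd(v[!is.na(v)]) else 0
    }
    for (cl in verdict_cols) {
      v <- sub[[cl]]
      out[[paste0("pct_", sub("^sig_", "", cl))]] <-
        if (all(is.na(v))) NA_real_ else rejection_proportion(as.logical(v[!is.na(v)]))
    }
    out
  })
  do.call(rbind, rows)
}

#' Simulate a synthetic cohort
#'
#' Convenience wrapper producing `n_subjects` paired REST/STAND marker-set
#' inputs from the preset family (`"HEALTHY"` or `"COVID"`), with
#' subject-specific seeds derived from `seed`.
#'
#' @param family `"HEALTHY"` or `"COVID"`.
#' @param n_subjects Number of subjects.
#' @param seed Master seed.
#' @param n_beats Beats per recording (default 1024, so that a random
#'   256-beat segment can be selected downstream).
#' @return List of lists with elements `subject_id`, `condition`, `series`.
#' @export
simulate_cohort <- function(family = c("HEALTHY", "COVID"), n_subjects = 40L,
                            seed = 1L, n_beats = 1024L) {
  family <- match.arg(family)
  out <- list()
  for (i in seq_len(n_subjects)) {
    for (cond in c("REST", "STAND")) {
      cfg <- sim_config(paste0(family, "_", cond), n_beats = n_beats,
                        seed = derive_seed(seed, i, if (cond == "REST") 0L else 1L))
      out[[length(out) + 1L]] <- list(
        subject_id = sprintf("%s%02d", substr(family, 1, 1), i),
        group = family, condition = cond,
        series = simulate_subject(cfg))
    }
  }
  out
}
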