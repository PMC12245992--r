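#' Per-phase summaries of a simulation
#'
#' For every protocol phase and ring: peak maximum-principal stress and the
#' cup displacement at which it occurs, stress at phase start and end, and
#' — for rest phases — the relaxation percentage
#' \eqn{100 (\sigma_{start} - \sigma_{end}) / \sigma_{start}}. A rest phase
#' starting at zero stress gets \code{NA} relaxation rather than a division
#' error.
#'
#' @param result a \code{"vad_result"} from [simulate_vad()].
#' @return data.frame: ring, phase, peak_sigma1, d_at_peak, sigma_start,
#'   sigma_end, relaxation_pct.
#' @export
phase_summaries <- function(result) {
  stopifnot(inherits(result, "vad_result"))
  ser <- result$series
  phases <- unique(ser$phase)
  out <- list()
  for (r in result$rings) {
    sig <- ser[[paste0("sigma1_", r$name)]]
    for (ph in phases) {
      i <- which(ser$phase == ph)
      s0 <- sig[i[1]]; s1 <- sig[i[length(i)]]
      relax <- NA_real_
      if (grepl("^rest", ph)) {
        relax <- if (s0 == 0) NA_real_ else 100 * (s0 - s1) / s0
      }
      out[[length(out) + 1]] <- data.frame(
        ring = r$name, phase = ph,
        peak_sigma1 = max(sig[i]),
        d_at_peak = ser$displacement[i][which.max(sig[i])],
        sigma_start = s0, sigma_end = s1,
        relaxation_pct = relax,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Run the full scenario sweep
#'
#' Simulates every scenario of a grid on one anatomy/material set.
#'
#' @param scenarios scenario grid from [build_scenarios()].
#' @param anatomy an \code{"anatomy_config"} (default [default_anatomy()]).
#' @param materials material set (default [default_materials()]).
#' @param dt,engagement_duration,total_descent protocol settings shared by
#'   all scenarios.
#' @return Named list of \code{"vad_result"} objects (names = scenario
#'   labels).
#' @export
run_sweep <- function(scenarios = build_scenarios(),
                      anatomy = default_anatomy(),
                      materials = default_materials(),
                      dt = 1, engagement_duration = 10800,
                      total_descent = 100) {
  stopifnot(inherits(anatomy, "anatomy_config"))
  res <- lapply(seq_len(nrow(scenarios)), function(i) {
    p <- pull_protocol(scenarios$contraction_s[i], scenarios$rest_s[i],
                       scenarios$n_pulls[i],
                       engagement_duration = engagement_duration,
                       total_descent = total_descent, dt = dt)
    simulate_vad(p, anatomy$head, anatomy$rings, materials)
  })
  names(res) <- scenarios$scenario
  res
}

#' Cross-scenario comparison table
#'
#' Peak pelvic-floor (levator-ring) stress, its displacement, and peak cup
#' force per scenario, sorted by (contraction, rest, pulls), plus the
#' pairwise percent-decrease matrix \eqn{100 (peak_A - peak_B)/peak_A}
#' (rows = A, columns = B; antisymmetric up to the A-denominator
#' convention).
#'
#' @param results named list of \code{"vad_result"} objects from
#'   [run_sweep()]; all must share one anatomy.
#' @param pfm_ring name of the viscoelastic (pelvic floor) ring.
#' @return data.frame of class \code{"scenario_comparison"} with attributes
#'   \code{pct_decrease} (matrix) and \code{force_pct_decrease}.
#' @export
compare_scenarios <- function(results, pfm_ring = "levator") {
  if (length(results) < 2) stop("need at least 2 scenarios to compare")
  c0 <- vapply(results, function(r) r$rings[[1]]$C0, numeric(1))
  rr <- vapply(results, function(r) r$head$R, numeric(1))
  if (diff(range(c0)) > 0 || diff(range(rr)) > 0) {
    stop("comparability error: scenarios were run on different anatomies")
  }
  rows <- lapply(names(results), function(nm) {
    res <- results[[nm]]
    p <- res$protocol
    man <- res$series[res$series$phase != "engagement", ]
    sig <- man[[paste0("sigma1_", pfm_ring)]]
    data.frame(scenario = nm,
               contraction_s = p$contraction_duration,
               rest_s = p$rest_duration, n_pulls = p$n_pulls,
               peak_sigma1 = max(sig),
               d_at_peak = man$displacement[which.max(sig)],
               peak_force = max(man$force_N),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$contraction_s, tab$rest_s, tab$n_pulls), ]
  rownames(tab) <- NULL
  pct <- function(v) {
    m <- 100 * outer(v, v, function(a, b) (a - b) / a)
    dimnames(m) <- list(tab$scenario, tab$scenario)
    m
  }
  structure(tab,
            pct_decrease = pct(tab$peak_sigma1),
            force_pct_decrease = pct(tab$peak_force),
            class = c("scenario_comparison", "data.frame"))
}

#' Tidy long-format series of a run
#'
#' One row per (time sample, ring): time_s, phase, displacement_mm, ring,
#' stretch, sigma1_MPa, force_N (total cup force, repeated across rings).
#'
#' @param result a \code{"vad_result"}.
#' @return data.frame.
#' @export
tidy_series <- function(result) {
  stopifnot(inherits(result, "vad_result"))
  ser <- result$series
  do.call(rbind, lapply(result$rings, function(r) {
    data.frame(time_s = ser$time, phase = ser$phase,
               displacement_mm = ser$displacement, ring = r$name,
               stretch = ser[[paste0("stretch_", r$name)]],
               sigma1_MPa = ser[[paste0("sigma1_", r$name)]],
               force_N = ser$force_N, stringsAsFactors = FALSE)
  }))
}
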