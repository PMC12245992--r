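#' Pull/rest traction protocol
#'
#' Timing of a vacuum-assisted extraction: a long engagement phase (the
#' prolonged-labor descent of the head into the pelvic floor, default 3 h)
#' followed by \code{n_pulls} traction pulls. Each pull ramps the cup
#' downward by \code{total_descent / n_pulls} mm over
#' \code{contraction_duration} s; consecutive pulls are separated by rests
#' of \code{rest_duration} s during which the cup holds position. No rest
#' follows the final pull (delivery is complete at its end).
#'
#' @param contraction_duration pull (contraction) duration, s.
#' @param rest_duration rest interval between pulls, s.
#' @param n_pulls number of pulls, integer >= 1.
#' @param engagement_duration engagement phase, s (default 10800 = 3 h).
#' @param total_descent total cup descent over the maneuver, mm (default 100).
#' @param dt maneuver-phase sampling step, s (default 1).
#' @param dt_engagement engagement-phase sampling step, s (default 60).
#' @return Object of class \code{"pull_protocol"}.
#' @export
pull_protocol <- function(contraction_duration, rest_duration, n_pulls,
                          engagement_duration = 10800, total_descent = 100,
                          dt = 1, dt_engagement = 60) {
  n_pulls <- as.integer(n_pulls)
  stopifnot(contraction_duration > 0, rest_duration > 0, n_pulls >= 1,
            engagement_duration > 0, total_descent >= 0, dt > 0,
            dt_engagement > 0)
  structure(list(contraction_duration = contraction_duration,
                 rest_duration = rest_duration,
                 n_pulls = n_pulls,
                 engagement_duration = engagement_duration,
                 total_descent = total_descent,
                 dt = dt, dt_engagement = dt_engagement),
            class = "pull_protocol")
}

#' @rdname pull_protocol
#' @param x,... print method arguments.
#' @export
print.pull_protocol <- function(x, ...) {
  cat(sprintf(
    "<pull_protocol> %d pulls x %gs, rest %gs, descent %g mm (engagement %g s)\n",
    x$n_pulls, x$contraction_duration, x$rest_duration, x$total_descent,
    x$engagement_duration))
  invisible(x)
}

#' Maneuver span of a protocol
#'
#' Active maneuver duration: n pulls plus the (n - 1) intervening rests.
#'
#' @param p a [pull_protocol()].
#' @return Duration in seconds.
#' @export
maneuver_duration <- function(p) {
  stopifnot(inherits(p, "pull_protocol"))
  p$n_pulls * p$contraction_duration + (p$n_pulls - 1) * p$rest_duration
}

#' Enumerate the scenario grid
#'
#' Cartesian product of contraction durations, rest intervals and pull
#' counts, with set semantics (duplicate inputs deduplicated) and a stable
#' lexicographic ordering by (contraction, rest, pulls).
#'
#' @param contractions contraction durations, s.
#' @param rests rest intervals, s.
#' @param pulls pull counts, integers.
#' @return data.frame with columns \code{scenario} (label),
#'   \code{contraction_s}, \code{rest_s}, \code{n_pulls}.
#' @examples
#' nrow(build_scenarios(c(60, 90), c(60, 180), 2:4))  # 12
#' @export
build_scenarios <- function(contractions = c(60, 90), rests = c(60, 180),
                            pulls = c(2, 3, 4)) {
  if (length(contractions) == 0 || length(rests) == 0 || length(pulls) == 0) {
    stop("configuration error: scenario factor sets must be non-empty")
  }
  contractions <- sort(unique(as.numeric(contractions)))
  rests <- sort(unique(as.numeric(rests)))
  pulls <- sort(unique(as.integer(pulls)))
  g <- expand.grid(n_pulls = pulls, rest_s = rests,
                   contraction_s = contractions,
                   KEEP.OUT.ATTRS = FALSE)
  g <- g[order(g$contraction_s, g$rest_s, g$n_pulls), ,
         drop = FALSE]
  rownames(g) <- NULL
  data.frame(
    scenario = sprintf("c%gs_r%gs_p%d", g$contraction_s, g$rest_s, g$n_pulls),
    contraction_s = g$contraction_s,
    rest_s = g$rest_s,
    n_pulls = g$n_pulls,
    stringsAsFactors = FALSE
  )
}

#' Cup displacement history of a protocol
#'
#' Samples the cup's vertical displacement d(t): zero throughout engagement
#' (the engagement descent is carried by the canal model's pre-stretch ramp,
#' the cup not yet being placed), then linear ramps of
#' \code{total_descent / n_pulls} mm per pull with constant plateaus during
#' rests. d is non-decreasing and ends exactly at \code{total_descent}.
#'
#' @param p a [pull_protocol()].
#' @return data.frame of class \code{"displacement_history"} with columns
#'   \code{time} (s), \code{displacement} (mm), \code{phase}
#'   (\code{"engagement"}, \code{"pull_k"}, \code{"rest_k"}).
#' @export
build_displacement_history <- function(p) {
  stopifnot(inherits(p, "pull_protocol"))
  if (p$n_pulls < 1) stop("configuration error: n_pulls must be >= 1")
  inc <- p$total_descent / p$n_pulls

  # engagement: [0, T_eng), sampled at dt_engagement, d = 0
  t_eng <- seq(0, p$engagement_duration - p$dt_engagement,
               by = p$dt_engagement)
  times <- t_eng
  disp <- rep(0, length(t_eng))
  phase <- rep("engagement", length(t_eng))

  t0 <- p$engagement_duration
  d0 <- 0
  for (k in seq_len(p$n_pulls)) {
    tp <- seq(0, p$contraction_duration, by = p$dt)
    if (tp[length(tp)] < p$contraction_duration) {
      tp <- c(tp, p$contraction_duration)
    }
    keep <- if (k == 1) TRUE else tp > 0   # avoid duplicating the boundary
    tp <- tp[keep]
    times <- c(times, t0 + tp)
    disp <- c(disp, d0 + inc * tp / p$contraction_duration)
    phase <- c(phase, rep(sprintf("pull_%d", k), length(tp)))
    t0 <- t0 + p$contraction_duration
    d0 <- d0 + inc
    if (k < p$n_pulls) {
      tr <- seq(p$dt, p$rest_duration, by = p$dt)
      if (tr[length(tr)] < p$rest_duration) tr <- c(tr, p$rest_duration)
      times <- c(times, t0 + tr)
      disp <- c(disp, rep(d0, length(tr)))
      phase <- c(phase, rep(sprintf("rest_%d", k), length(tr)))
      t0 <- t0 + p$rest_duration
    }
  }
  disp[length(disp)] <- p$total_descent   # exact endpoint
  out <- data.frame(time = times, displacement = disp, phase = phase,
                    stringsAsFactors = FALSE)
  class(out) <- c("displacement_history", "data.frame")
  out
}
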