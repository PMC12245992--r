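# run expr with a local, restored RNG stream so generators are pure
# functions of (parameters, seed)
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Default synthetic anatomy
#'
#' Spheroidal head of radius 47.5 mm with hiatal rings sized and stationed
#' so that the kinematic peak stretches and their cup displacements match
#' the study's anchors: levator hiatus peak stretch 2.09 at 69.91 mm
#' descent, urogenital hiatus peak stretch 3.01 at 79.51 mm. For a
#' symmetric profile the peak occurs when the equator crosses the ring
#' plane, so the stations are the anchor displacements and the ring
#' circumferences are \eqn{C_0 = 2\pi R / \lambda_{peak}} — the anchors are
#' reproduced by construction (calibration, not prediction). Deterministic:
#' repeated calls give identical configurations.
#'
#' @param R head radius (mm).
#' @param lambda_eng engagement pre-stretch applied to both rings.
#' @param area_levator,area_urogenital effective ring areas (mm^2) for the
#'   cup-force projection.
#' @return Object of class \code{"anatomy_config"}: list with \code{head}
#'   and \code{rings}.
#' @export
default_anatomy <- function(R = 47.5, lambda_eng = 1.3,
                            area_levator = 150, area_urogenital = 100) {
  head <- spherical_head(R = R)
  rings <- list(
    hiatus_ring("levator", C0 = 2 * pi * R / 2.09, z_ring = 69.91,
                material = "pfm-martins-viscoelastic",
                lambda_eng = lambda_eng, area = area_levator),
    hiatus_ring("urogenital", C0 = 2 * pi * R / 3.01, z_ring = 79.51,
                material = "perineum-linear-elastic",
                lambda_eng = lambda_eng, area = area_urogenital)
  )
  structure(list(head = head, rings = rings), class = "anatomy_config")
}

#' Peak kinematic stretch of each ring in an anatomy
#'
#' Sweeps the cup displacement over a fine grid and reports each ring's
#' maximum kinematic stretch and the displacement at which it occurs.
#' Material-independent.
#'
#' @param anatomy an \code{"anatomy_config"}.
#' @param d_grid displacement sweep (mm).
#' @return data.frame: ring, peak_stretch, d_at_peak.
#' @export
anatomy_peak_stretches <- function(anatomy,
                                   d_grid = seq(0, 100, by = 0.01)) {
  stopifnot(inherits(anatomy, "anatomy_config"))
  do.call(rbind, lapply(anatomy$rings, function(r) {
    lam <- ring_stretch_at(d_grid, anatomy$head, r)
    data.frame(ring = r$name, peak_stretch = max(lam),
               d_at_peak = d_grid[which.max(lam)],
               stringsAsFactors = FALSE)
  }))
}

#' Perturbed anatomy cohort
#'
#' Draws n anatomies around the default: the head radius and each ring
#' circumference are multiplied by independent mean-1 lognormal factors.
#' Each factor's coefficient of variation is \code{cv / sqrt(2)} so that
#' the derived peak kinematic stretch (proportional to the ratio R / C0 of
#' two independent factors) has cohort coefficient of variation
#' approximately \code{cv} — \code{cv} dials the variability of the
#' quantity the cohort is meant to vary. Supports sensitivity studies over
#' patient-to-patient geometric variation. Reproducible under a fixed seed.
#'
#' @param n cohort size, >= 1.
#' @param cv coefficient of variation of the perturbation factors, in
#'   \[0, 0.3).
#' @param seed RNG seed.
#' @return List of \code{"anatomy_config"} objects.
#' @export
perturbed_cohort <- function(n, cv, seed = 1) {
  stopifnot(n >= 1)
  if (cv < 0 || cv >= 0.3) {
    stop("configuration error: cv must be in [0, 0.3)")
  }
  base <- default_anatomy()
  if (cv == 0) return(rep(list(base), n))
  sdlog <- sqrt(log(1 + cv^2 / 2))
  meanlog <- -sdlog^2 / 2                 # mean-1 lognormal
  with_local_seed(seed, {
    lapply(seq_len(n), function(i) {
      fR <- stats::rlnorm(1, meanlog, sdlog)
      fC <- stats::rlnorm(length(base$rings), meanlog, sdlog)
      a <- default_anatomy(R = base$head$R * fR)
      for (j in seq_along(a$rings)) {
        # default_anatomy rescales C0 with R; perturb around the base C0
        a$rings[[j]]$C0 <- base$rings[[j]]$C0 * fC[j]
      }
      a
    })
  })
}

#' Synthetic noisy plate-compression curve
#'
#' Forward Hertz forces on a deflection grid spanning (0, max_deflection]
#' with independent multiplicative Gaussian noise, \eqn{F_i =
#' F_{model}(\delta_i) (1 + cv \, z_i)}. Stands in for the neonatal
#' compression measurements the calibration replicates (available only as
#' published figures).
#'
#' @param E_true true Young's modulus (MPa).
#' @param n_points number of points, >= 3.
#' @param noise_cv multiplicative noise coefficient of variation.
#' @param seed RNG seed.
#' @param nu,R fixed Poisson's ratio and radius (mm).
#' @param max_deflection largest deflection (mm), default 5.
#' @return A [compression_curve()].
#' @examples
#' cal <- calibrate_young_modulus(
#'   synthetic_compression_curve(1.1, 20, 0.02, seed = 7))
#' cal$E
#' @export
synthetic_compression_curve <- function(E_true, n_points = 20,
                                        noise_cv = 0, seed = 1,
                                        nu = 0.25, R = 45,
                                        max_deflection = 5) {
  stopifnot(E_true > 0, n_points >= 3, noise_cv >= 0)
  delta <- seq(max_deflection / n_points, max_deflection,
               length.out = n_points)
  f <- plate_compression_force(E = E_true, nu = nu, R = R, delta = delta)
  if (noise_cv > 0) {
    f <- with_local_seed(seed,
                         f * (1 + noise_cv * stats::rnorm(n_points)))
    f <- pmax(f, 0)
  }
  compression_curve(delta, f, radius = R, noise_cv = noise_cv,
                    seed = if (noise_cv > 0) seed else NA)
}
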