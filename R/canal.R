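#' Axisymmetric fetal-head geometry
#'
#' The head is represented by its axisymmetric surface profile
#' \eqn{\rho(u)}: the section radius (mm) as a function of the axial
#' coordinate u (mm) measured from the equator (widest section), positive
#' toward the leading pole. The head is treated as quasi-rigid for ring
#' kinematics — its Young's modulus (about 1.1 MPa) is orders of magnitude
#' above the tissue moduli — and translates with the cup, so after
#' engagement the equator sits at axial station \code{d + offset} when the
#' cup has descended d mm.
#'
#' @param s axial sample grid (mm), strictly increasing, containing 0.
#' @param rho profile radii at \code{s} (mm), all >= 0, attaining the
#'   maximum radius.
#' @param offset rigid-body axial offset of the equator at d = 0 (mm).
#' @return Object of class \code{"head_geometry"} with fields \code{s},
#'   \code{rho}, \code{R} (max radius), \code{L} (axial length),
#'   \code{offset}.
#' @export
head_geometry <- function(s, rho, offset = 0) {
  stopifnot(is.numeric(s), is.numeric(rho), length(s) == length(rho),
            length(s) >= 3, all(diff(s) > 0), all(rho >= 0),
            min(abs(s)) < min(diff(s)))
  structure(list(s = s, rho = rho, R = max(rho), L = diff(range(s)),
                 offset = offset),
            class = "head_geometry")
}

#' @rdname head_geometry
#' @param R sphere radius (mm).
#' @param ds profile sampling step (mm).
#' @export
spherical_head <- function(R = 47.5, ds = 0.1, offset = 0) {
  stopifnot(R > 0, ds > 0, ds < R)
  u <- seq(-R, R, by = ds)
  if (u[length(u)] < R) u <- c(u, R)
  u <- sort(unique(c(u, 0)))              # ensure the equator is sampled
  head_geometry(s = u, rho = sqrt(pmax(R^2 - u^2, 0)), offset = offset)
}

# profile radius at axial coordinate u (0 outside the support)
profile_radius <- function(head, u) {
  out <- rep(0, length(u))
  inside <- u >= head$s[1] & u <= head$s[length(head$s)]
  if (any(inside)) {
    out[inside] <- stats::approx(head$s, head$rho, xout = u[inside],
                                 rule = 2)$y
  }
  out
}

# sine of the local profile slope angle at axial coordinate u
profile_sin_alpha <- function(head, u) {
  drho <- diff(head$rho) / diff(head$s)
  mid <- (head$s[-1] + head$s[-length(head$s)]) / 2
  out <- rep(0, length(u))
  inside <- u >= head$s[1] & u <= head$s[length(head$s)]
  if (any(inside)) {
    g <- stats::approx(mid, drho, xout = u[inside], rule = 2)$y
    out[inside] <- abs(g) / sqrt(1 + g^2)
  }
  out
}

#' Hiatal ring descriptor
#'
#' A material ring standing in for a measurement path on the pelvic floor:
#' the levator hiatus (pelvic floor muscle, viscoelastic) or the urogenital
#' hiatus (perineal structures, linear elastic). The ring lies in a plane at
#' axial station \code{z_ring} (mm, same axis and origin as cup
#' displacement) and has undeformed circumference \code{C0} (mm). During
#' engagement its stretch is ramped from 1 to the pre-stretch
#' \code{lambda_eng}; during the maneuver it follows the kinematic
#' distension imposed by the head section crossing its plane.
#'
#' @param name ring label, \code{"levator"} or \code{"urogenital"}.
#' @param C0 undeformed circumference (mm), > 0.
#' @param z_ring axial station of the ring plane (mm).
#' @param material \code{"pfm-martins-viscoelastic"} or
#'   \code{"perineum-linear-elastic"}.
#' @param lambda_eng engagement pre-stretch, >= 1 (default 1.3).
#' @param area effective load-bearing cross-section area (mm^2) used by the
#'   cup-force projection.
#' @return Object of class \code{"hiatus_ring"}.
#' @export
hiatus_ring <- function(name, C0, z_ring,
                        material = c("pfm-martins-viscoelastic",
                                     "perineum-linear-elastic"),
                        lambda_eng = 1.3, area = 100) {
  material <- match.arg(material)
  stopifnot(C0 > 0, lambda_eng >= 1, area > 0)
  structure(list(name = name, C0 = C0, z_ring = z_ring, material = material,
                 lambda_eng = lambda_eng, area = area),
            class = "hiatus_ring")
}

#' Kinematic ring stretch at a cup displacement
#'
#' Circumferential stretch imposed on a ring by the head section currently
#' crossing its plane: \eqn{\lambda = \max(1, 2\pi\rho(z_{ring} - d -
#' \mathrm{offset}) / C_0)}; \eqn{\lambda = 1} when no head section
#' intersects the ring plane. Purely geometric — independent of any material
#' assignment.
#'
#' @param d cup displacement(s), mm (vectorised).
#' @param head a [head_geometry()].
#' @param ring a [hiatus_ring()].
#' @return Stretch value(s), >= 1.
#' @examples
#' h <- spherical_head(R = 47.5)
#' r <- hiatus_ring("levator", C0 = 2 * pi * 25, z_ring = 60)
#' ring_stretch_at(40, h, r)   # sqrt(47.5^2 - 20^2) / 25
#' @export
ring_stretch_at <- function(d, head, ring) {
  stopifnot(inherits(head, "head_geometry"), inherits(ring, "hiatus_ring"))
  u <- ring$z_ring - (d + head$offset)
  pmax(1, 2 * pi * profile_radius(head, u) / ring$C0)
}

#' Default material set for the reduced model
#'
#' Pelvic floor muscle: transversely isotropic hyperelastic with matrix and
#' fiber Maxwell branch sets. Perineal structures (perineal body /
#' bulbospongiosus): linear elastic with E = 23.8 kPa, nu = 0.49, no
#' viscoelasticity.
#'
#' @return Named list with \code{pfm}, \code{perineum},
#'   \code{branches_matrix}, \code{branches_fiber}.
#' @export
default_materials <- function() {
  list(pfm = martins_params(),
       perineum = linear_elastic_params(E = 0.0238, nu = 0.49, unit = "MPa"),
       branches_matrix = matrix_branches(),
       branches_fiber = fiber_branches())
}

#' Simulate a vacuum-assisted extraction on the reduced ring model
#'
#' Drives both hiatal rings through the displacement history of a
#' [pull_protocol()]: the engagement phase ramps each ring's stretch
#' linearly from 1 to its pre-stretch \code{lambda_eng} (viscoelastic
#' history accumulates during this 3 h ramp); the maneuver phase sets
#' \eqn{\lambda(t) = \max(\lambda_{eng}, \lambda_{kin}(d(t)))} from the
#' head kinematics. Ring stress is evaluated in incompressible uniaxial
#' (hoop) mode: the muscle ring through [uniaxial_stress_split()] plus the
#' generalized-Maxwell overstress recurrence (matrix and fiber branch sets
#' shadowing their own contributions), the perineal ring through the linear
#' elastic law. The cup traction force is the membrane projection computed
#' by [cup_force()].
#'
#' @param protocol a [pull_protocol()].
#' @param head a [head_geometry()].
#' @param rings list of [hiatus_ring()] objects.
#' @param materials material set as from [default_materials()].
#' @return Object of class \code{"vad_result"}: list with \code{series}
#'   (data.frame: time, phase, displacement, per-ring \code{stretch_*} and
#'   \code{sigma1_*} columns, \code{force_N}), plus the inputs.
#' @export
simulate_vad <- function(protocol, head, rings,
                         materials = default_materials()) {
  stopifnot(inherits(protocol, "pull_protocol"),
            inherits(head, "head_geometry"))
  hist <- build_displacement_history(protocol)
  nT <- nrow(hist)
  nr <- length(rings)
  ring_names <- vapply(rings, function(r) r$name, character(1))

  # warn (once) if the head can never distend a ring
  for (r in rings) {
    if (2 * pi * head$R / r$C0 <= 1) {
      warning("head never stretches ring '", r$name,
              "' (2*pi*R <= C0); stretch stays at 1")
    }
  }

  eng <- hist$phase == "engagement"
  lam <- matrix(1, nT, nr, dimnames = list(NULL, ring_names))
  for (j in seq_len(nr)) {
    r <- rings[[j]]
    # engagement ramp 1 -> lambda_eng; maneuver: kinematic, floored at
    # lambda_eng (the engaged head holds the pre-distension)
    frac <- hist$time[eng] / protocol$engagement_duration
    lam[eng, j] <- 1 + (r$lambda_eng - 1) * frac
    lam[!eng, j] <- pmax(r$lambda_eng,
                         ring_stretch_at(hist$displacement[!eng], head, r))
  }

  sig <- matrix(0, nT, nr, dimnames = list(NULL, ring_names))
  for (j in seq_len(nr)) {
    r <- rings[[j]]
    if (r$material == "perineum-linear-elastic") {
      sig[, j] <- linear_elastic_stress(lam[, j] - 1, materials$perineum)
    } else {
      eqs <- uniaxial_stress_split(lam[, j], materials$pfm)
      sm <- visco_state(materials$branches_matrix)
      sf <- visco_state(materials$branches_fiber)
      over <- numeric(nT)
      for (k in 2:nT) {
        dt <- hist$time[k] - hist$time[k - 1]
        sm <- update_overstress(sm, eqs$matrix[k] - eqs$matrix[k - 1], dt)
        sf <- update_overstress(sf, eqs$fiber[k] - eqs$fiber[k - 1], dt)
        over[k] <- total_overstress(sm) + total_overstress(sf)
      }
      sig[, j] <- eqs$matrix + eqs$fiber + over
    }
  }

  series <- data.frame(time = hist$time, phase = hist$phase,
                       displacement = hist$displacement,
                       stringsAsFactors = FALSE)
  for (j in seq_len(nr)) {
    series[[paste0("stretch_", ring_names[j])]] <- lam[, j]
    series[[paste0("sigma1_", ring_names[j])]] <- sig[, j]
  }
  res <- structure(list(series = series, protocol = protocol, head = head,
                        rings = rings, materials = materials),
                   class = "vad_result")
  res$series$force_N <- cup_force(res)
  res
}

#' @rdname simulate_vad
#' @param x,... print method arguments.
#' @export
print.vad_result <- function(x, ...) {
  pk <- peak_summary(x)
  cat("<vad_result>", nrow(x$series), "samples,",
      length(x$rings), "rings\n")
  print(pk, row.names = FALSE)
  invisible(x)
}

#' Cup traction force series
#'
#' Axial (y-direction) traction transmitted through the rings, modeled as a
#' membrane-tension projection: \eqn{F_y(t) = \sum_{rings} \sigma_1(t)
#' A_{ring} \sin\alpha(t)}, with \eqn{\alpha} the local slope angle of the
#' head profile at the ring plane and \eqn{A_{ring}} the ring's effective
#' cross-section area. Only the head's leading face resists traction: once
#' the equator has passed a ring plane the hoop tension's axial component
#' acts along the descent and no longer opposes it, so that ring's
#' contribution drops to zero. A ring out of kinematic contact (or facing
#' a cylindrical section, \eqn{\alpha = 0}) likewise contributes nothing.
#' Absolute newton values depend on the configured areas; only
#' cross-scenario orderings are meaningful.
#'
#' @param result a \code{"vad_result"} from [simulate_vad()].
#' @return Numeric force series (N), one value per time sample, >= 0.
#' @export
cup_force <- function(result) {
  stopifnot(inherits(result, "vad_result"))
  ser <- result$series
  head <- result$head
  f <- numeric(nrow(ser))
  for (r in result$rings) {
    if (is.null(r$area)) stop("configuration error: ring '", r$name,
                              "' has no effective area")
    u <- r$z_ring - (ser$displacement + head$offset)
    lam_kin <- ring_stretch_at(ser$displacement, head, r)
    contact <- lam_kin > 1 & u > 0 & ser$phase != "engagement"
    sa <- profile_sin_alpha(head, u)
    sig <- ser[[paste0("sigma1_", r$name)]]
    f <- f + ifelse(contact, sig * r$area * sa, 0)
  }
  f
}

#' Stress as a function of cup displacement
#'
#' Evaluates a ring's stress-vs-displacement curve on a reference
#' displacement grid. For a linear elastic ring the curve follows directly
#' from the ring kinematics and the equilibrium law (exact, and by
#' construction independent of protocol timing — the reduced-model analogue
#' of elastic perineal structures showing identical stress across
#' scenarios). For the viscoelastic ring the simulated time series is
#' interpolated against displacement (pull phases only; the curve is
#' protocol-dependent).
#'
#' @param result a \code{"vad_result"}.
#' @param ring_name name of the ring.
#' @param d_grid displacement grid (mm), default \code{seq(0, 100, 0.5)}.
#' @return data.frame with columns \code{displacement}, \code{sigma1}.
#' @export
ring_stress_vs_displacement <- function(result, ring_name,
                                        d_grid = seq(0, 100, by = 0.5)) {
  stopifnot(inherits(result, "vad_result"))
  ring <- NULL
  for (r in result$rings) if (r$name == ring_name) ring <- r
  if (is.null(ring)) stop("unknown ring: ", ring_name)
  if (ring$material == "perineum-linear-elastic") {
    lam <- pmax(ring$lambda_eng,
                ring_stretch_at(d_grid, result$head, ring))
    sig <- linear_elastic_stress(lam - 1, result$materials$perineum)
  } else {
    ser <- result$series[grepl("^pull", result$series$phase), ]
    sig <- stats::approx(ser$displacement,
                         ser[[paste0("sigma1_", ring_name)]],
                         xout = d_grid, ties = "ordered", rule = 2)$y
  }
  data.frame(displacement = d_grid, sigma1 = sig)
}

#' Peak stress/stretch/force summary of a run
#'
#' @param result a \code{"vad_result"}.
#' @return data.frame: one row per ring with peak stretch, peak stress and
#'   their displacements, plus the peak cup force as attributes
#'   \code{peak_force} / \code{peak_force_displacement}.
#' @export
peak_summary <- function(result) {
  stopifnot(inherits(result, "vad_result"))
  ser <- result$series
  man <- ser[ser$phase != "engagement", ]
  out <- do.call(rbind, lapply(result$rings, function(r) {
    lam <- man[[paste0("stretch_", r$name)]]
    sig <- man[[paste0("sigma1_", r$name)]]
    data.frame(ring = r$name,
               peak_stretch = max(lam),
               d_at_peak_stretch = man$displacement[which.max(lam)],
               peak_sigma1 = max(sig),
               d_at_peak_sigma1 = man$displacement[which.max(sig)],
               stringsAsFactors = FALSE)
  }))
  attr(out, "peak_force") <- max(man$force_N)
  attr(out, "peak_force_displacement") <- man$displacement[which.max(man$force_N)]
  out
}
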