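# Parametric biventricular phantom with analytic ground truth.
#
# The LV blood pool is a half-ellipsoid (base plane z = 0, apex at z = L) whose
# in-plane semi-axis follows the prescribed volume curve; the myocardium is a
# concentric shell of constant wall volume whose epicardial surface extends
# t_apex mm beyond the pool apex. The RV is a crescent wrapped around the LV
# epicardium (an annular sector in every short-axis section) whose
# cross-sectional area profile is prescribed analytically, so both chambers
# have closed-form volume curves. Deformation is purely radial about the long
# axis, giving closed-form displacement fields and mid-wall circumferential
# strain.

#' Analytic ventricular volume-curve model
#'
#' A smooth (C1) periodic cycle: monotone raised-cosine ejection from EDV to
#' ESV on `[0, t_es]`, an explicit diastasis, and E- and A-wave refilling as
#' two localized raised-cosine pulses in dV/dt. All times are fractions of the
#' RR interval. Peak rates and the atrial contribution have closed forms:
#' `PER = 2 SV / t_es`, `PEFR = 2 E / w_e`, `PAFR = 2 A / w_a`, `AC = A`
#' (per RR fraction; divide by RR seconds for ml/s).
#'
#' @param edv,esv end-diastolic and end-systolic volumes, ml (`edv > esv > 0`).
#' @param t_es end-systolic time, fraction of RR.
#' @param e_peak_time,a_peak_time centers of the E- and A-wave dV/dt pulses,
#'   fractions of RR.
#' @param wave_widths length-2 numeric, full widths of the E- and A-wave
#'   pulses as fractions of RR.
#' @param a_fraction fraction of the stroke volume refilled by the A wave
#'   (used when `e_wave_amplitude`/`a_wave_amplitude` are not given).
#' @param e_wave_amplitude,a_wave_amplitude explicit wave volumes in ml; must
#'   sum to `edv - esv` within 0.1 ml.
#' @return object of class `volume_curve_model`.
#' @export
volume_curve_model <- function(edv, esv, t_es = 0.35,
                               e_peak_time = 0.5, a_peak_time = 0.85,
                               wave_widths = c(0.2, 0.15),
                               a_fraction = 0.3,
                               e_wave_amplitude = NULL,
                               a_wave_amplitude = NULL) {
  if (!(edv > esv && esv > 0)) stop("need edv > esv > 0")
  sv <- edv - esv
  if (is.null(e_wave_amplitude)) {
    a_wave_amplitude <- a_fraction * sv
    e_wave_amplitude <- sv - a_wave_amplitude
  }
  if (abs(e_wave_amplitude + a_wave_amplitude - sv) > 0.1)
    stop("wave amplitudes must sum to the stroke volume (within 0.1 ml)")
  w <- wave_widths
  e_start <- e_peak_time - w[1] / 2
  a_start <- a_peak_time - w[2] / 2
  if (!(0 < t_es && t_es <= e_start && e_start + w[1] <= a_start &&
        a_start + w[2] <= 1))
    stop("phases must be ordered: ejection, E wave, A wave, all within one RR")
  structure(list(edv = edv, esv = esv, t_es = t_es,
                 e_wave_amplitude = e_wave_amplitude,
                 a_wave_amplitude = a_wave_amplitude,
                 e_peak_time = e_peak_time, a_peak_time = a_peak_time,
                 wave_widths = w),
            class = "volume_curve_model")
}

# integral of a unit-area raised-cosine pulse on [t0, t0+w], evaluated at t
raised_cos_cdf <- function(t, t0, w) {
  u <- pmin(pmax((t - t0) / w, 0), 1)
  u - sin(2 * pi * u) / (2 * pi)
}

# its density (the pulse itself), peak 2/w at t0 + w/2
raised_cos_pdf <- function(t, t0, w) {
  inside <- t >= t0 & t <= t0 + w
  ifelse(inside, (1 - cos(2 * pi * (t - t0) / w)) / w, 0)
}

#' Evaluate the analytic volume curve
#'
#' @param model a [volume_curve_model()].
#' @param t time as fraction of RR, in `[0, 1]`; vectorized.
#' @return volume in ml.
#' @export
analytic_volume <- function(model, t) {
  if (any(t < 0 | t > 1)) stop("t must lie in [0, 1]")
  m <- model
  sv <- m$edv - m$esv
  m$edv -
    sv * raised_cos_cdf(t, 0, m$t_es) +
    m$e_wave_amplitude * raised_cos_cdf(t, m$e_peak_time - m$wave_widths[1] / 2,
                                        m$wave_widths[1]) +
    m$a_wave_amplitude * raised_cos_cdf(t, m$a_peak_time - m$wave_widths[2] / 2,
                                        m$wave_widths[2])
}

#' Analytic dV/dt of the volume-curve model (ml per RR fraction)
#' @inheritParams analytic_volume
#' @export
analytic_dvdt <- function(model, t) {
  m <- model
  sv <- m$edv - m$esv
  -sv * raised_cos_pdf(t, 0, m$t_es) +
    m$e_wave_amplitude * raised_cos_pdf(t, m$e_peak_time - m$wave_widths[1] / 2,
                                        m$wave_widths[1]) +
    m$a_wave_amplitude * raised_cos_pdf(t, m$a_peak_time - m$wave_widths[2] / 2,
                                        m$wave_widths[2])
}

#' Closed-form cycle parameters of a volume-curve model
#'
#' @param model a [volume_curve_model()].
#' @param rr_interval RR interval in seconds (converts rates to ml/s).
#' @return list with edv, esv, sv, ef (%), per, pefr, pafr (ml/s), ac_ml,
#'   ac_pct_sv.
#' @export
analytic_cycle_parameters <- function(model, rr_interval = 1) {
  m <- model
  sv <- m$edv - m$esv
  list(edv = m$edv, esv = m$esv, sv = sv, ef = 100 * sv / m$edv,
       per = 2 * sv / (m$t_es * rr_interval),
       pefr = 2 * m$e_wave_amplitude / (m$wave_widths[1] * rr_interval),
       pafr = 2 * m$a_wave_amplitude / (m$wave_widths[2] * rr_interval),
       ac_ml = m$a_wave_amplitude,
       ac_pct_sv = 100 * m$a_wave_amplitude / sv)
}

#' Phantom specification
#'
#' Geometry and acquisition parameters for [build_phantom()]. Defaults emulate
#' a UK-Biobank-style cine acquisition (50 frames, 8 mm slices with 2 mm gap)
#' of a healthy male heart (Table-style mean volumes).
#'
#' @param lv,rv [volume_curve_model()] for each chamber.
#' @param lv_wall_volume LV myocardial shell volume in ml, constant over the
#'   cycle.
#' @param lv_length base-to-apex pool length in mm.
#' @param apex_wall thickness of myocardium beyond the pool apex, mm.
#' @param n_frames frames per cardiac cycle.
#' @param voxel_size in-plane voxel size in mm (isotropic in-plane).
#' @param slice_thickness,slice_gap SAX slice geometry, mm.
#' @param n_sax_slices number of SAX slices; default covers the epicardium.
#' @param rr_interval RR interval, s.
#' @param rv_gap,rv_span RV crescent: radial gap to the epicardium (mm) and
#'   angular span (radians) centered on the free wall.
#' @param rv_length RV base-to-apex length, mm; default `0.9 * lv_length`.
#' @param with_fields also rasterize ground-truth displacement fields.
#' @param with_images also synthesize intensity images (for the built-in
#'   tracker), with mild seeded noise.
#' @param subject a [subject_meta()]; its `rr_interval` is overridden.
#' @param seed integer; fixes all stochastic texture.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(lv = volume_curve_model(179, 77),
                         rv = volume_curve_model(196, 94),
                         lv_wall_volume = 100, lv_length = 90, apex_wall = 8,
                         n_frames = 50, voxel_size = 2,
                         slice_thickness = 8, slice_gap = 2,
                         n_sax_slices = NULL, rr_interval = 1,
                         rv_gap = 2, rv_span = 2.4, rv_length = NULL,
                         with_fields = FALSE, with_images = FALSE,
                         subject = subject_meta(sex = "M", age = 50,
                                                height = 171, weight = 74),
                         seed = 1L) {
  stopifnot(inherits(lv, "volume_curve_model"), inherits(rv, "volume_curve_model"))
  dz <- slice_thickness + slice_gap
  l_epi <- lv_length + apex_wall
  if (is.null(n_sax_slices)) n_sax_slices <- ceiling(l_epi / dz)
  if (is.null(rv_length)) rv_length <- 0.9 * lv_length
  subject$rr_interval <- rr_interval
  structure(list(lv = lv, rv = rv, lv_wall_volume = lv_wall_volume,
                 lv_length = lv_length, apex_wall = apex_wall,
                 n_frames = n_frames, voxel_size = voxel_size,
                 slice_thickness = slice_thickness, slice_gap = slice_gap,
                 n_sax_slices = n_sax_slices, rr_interval = rr_interval,
                 rv_gap = rv_gap, rv_span = rv_span, rv_length = rv_length,
                 with_fields = with_fields, with_images = with_images,
                 subject = subject, seed = as.integer(seed)),
            class = "phantom_spec")
}

# --- analytic geometry helpers -------------------------------------------

# LV pool in-plane semi-axis for a given pool volume (half-ellipsoid)
pool_semi_axis <- function(v_ml, lv_length) sqrt(3 * v_ml * 1000 / (2 * pi * lv_length))

# epicardial semi-axis keeping shell volume constant, outer length l_epi
epi_semi_axis <- function(a_pool, lv_length, l_epi, wall_ml) {
  sqrt((3 * wall_ml * 1000 / (2 * pi) + a_pool^2 * lv_length) / l_epi)
}

# squared ellipsoid radius profile at height z (0 outside [0, L])
radius_sq_profile <- function(a, L, z) {
  f <- 1 - (z / L)^2
  a^2 * pmax(f, 0) * (z >= 0 & z <= L)
}

phantom_geometry <- function(spec) {
  nf <- spec$n_frames
  tfrac <- (seq_len(nf) - 1) / nf
  v_lv <- analytic_volume(spec$lv, tfrac)
  v_rv <- analytic_volume(spec$rv, tfrac)
  a_pool <- pool_semi_axis(v_lv, spec$lv_length)
  l_epi <- spec$lv_length + spec$apex_wall
  a_epi <- epi_semi_axis(a_pool, spec$lv_length, l_epi, spec$lv_wall_volume)
  list(tfrac = tfrac, v_lv = v_lv, v_rv = v_rv,
       a_pool = a_pool, a_epi = a_epi, l_epi = l_epi)
}

# RV annular-sector bounds at height z (scalars per (z, frame))
rv_bounds <- function(spec, geo, z, frame) {
  if (z < 0 || z > spec$rv_length) return(NULL)
  r_epi2 <- radius_sq_profile(geo$a_epi[frame], geo$l_epi, z)
  r_in <- sqrt(r_epi2) + spec$rv_gap
  area <- geo$v_rv[frame] * 1000 * 3 / (2 * spec$rv_length) *
    (1 - (z / spec$rv_length)^2)
  r_out <- sqrt(r_in^2 + 2 * area / spec$rv_span)
  c(r_in = r_in, r_out = r_out)
}

# --- rasterization --------------------------------------------------------

#' Build a phantom cine study with ground truth
#'
#' Rasterizes the parametric phantom onto a SAX stack and exact planar 2- and
#' 4-chamber LAX resamplings through the long axis, and returns the study
#' together with its analytic ground truth: per-frame LV/RV volumes,
#' closed-form cycle parameters, mid-wall circumferential strain, and
#' (optionally) dense displacement fields mapping ED voxel centers to their
#' frame-t positions.
#'
#' @param spec a [phantom_spec()].
#' @return object of class `phantom`: list with `study` (a `cine_study`),
#'   `truth` (curves, parameters, strain, fields) and `spec`.
#' @export
build_phantom <- function(spec) {
  geo <- phantom_geometry(spec)
  nf <- spec$n_frames
  h <- spec$voxel_size
  dz <- spec$slice_thickness + spec$slice_gap

  # grid half-extent: widest RV outer radius over cycle + margin
  r_out_max <- max(vapply(seq_len(nf), function(f) {
    b <- rv_bounds(spec, geo, 0, f)
    if (is.null(b)) 0 else b["r_out"]
  }, numeric(1)), max(geo$a_epi))
  half <- r_out_max + 6
  xg <- seq(-half, half, by = h)
  nx <- length(xg)
  z_slices <- dz / 2 + dz * (seq_len(spec$n_sax_slices) - 1)
  if (max(z_slices) < geo$l_epi - dz)
    stop("geometry overflow: SAX stack does not cover the ventricle")

  frame_times <- geo$tfrac * spec$rr_interval

  # in-plane squared radius and angle, shared by all slices/frames
  X <- matrix(xg, nx, nx)
  Y <- matrix(xg, nx, nx, byrow = TRUE)
  R2 <- X^2 + Y^2
  TH <- atan2(Y, X)
  # RV free wall centered at angle pi (negative x side)
  in_span <- abs(atan2(sin(TH - pi), cos(TH - pi))) <= spec$rv_span / 2

  sax <- array(0L, dim = c(nx, nx, length(z_slices), nf))
  for (f in seq_len(nf)) {
    for (s in seq_along(z_slices)) {
      z <- z_slices[s]
      re2 <- radius_sq_profile(geo$a_pool[f], spec$lv_length, z)
      rp2 <- radius_sq_profile(geo$a_epi[f], geo$l_epi, z)
      lab <- matrix(0L, nx, nx)
      lab[R2 <= rp2] <- 2L
      if (re2 > 0) lab[R2 <= re2] <- 1L
      b <- rv_bounds(spec, geo, z, f)
      if (!is.null(b) && b["r_out"] > b["r_in"])
        lab[in_span & R2 >= b["r_in"]^2 & R2 <= b["r_out"]^2] <- 3L
      sax[, , s, f] <- lab
    }
  }
  aff_sax <- diag(4)
  aff_sax[1, 1] <- h; aff_sax[2, 2] <- h; aff_sax[3, 3] <- dz
  aff_sax[1:3, 4] <- c(-half, -half, z_slices[1])
  sax_stack <- labelled_stack(sax, aff_sax, c(h, h), spec$slice_thickness,
                              spec$slice_gap, frame_times, "SAX")

  # LAX grids: rows = in-plane transverse axis, cols = long axis (z)
  zg <- seq(-10, geo$l_epi + 10, by = h)
  nzc <- length(zg)
  lax_label <- function(transverse_is_x) {
    arr <- array(0L, dim = c(nx, nzc, 1L, nf))
    for (f in seq_len(nf)) {
      re2 <- radius_sq_profile(geo$a_pool[f], spec$lv_length, zg)
      rp2 <- radius_sq_profile(geo$a_epi[f], geo$l_epi, zg)
      lab <- matrix(0L, nx, nzc)
      X2 <- xg^2
      myo <- outer(X2, rp2, `<=`) & outer(rep(TRUE, nx), rp2 > 0)
      pool <- outer(X2, re2, `<=`) & outer(rep(TRUE, nx), re2 > 0)
      lab[myo] <- 2L
      lab[pool] <- 1L
      if (transverse_is_x) {  # 4CH plane (y = 0) cuts the RV at angle pi
        for (j in seq_len(nzc)) {
          b <- rv_bounds(spec, geo, zg[j], f)
          if (!is.null(b) && b["r_out"] > b["r_in"]) {
            sel <- xg <= -b["r_in"] & xg >= -b["r_out"]
            lab[sel, j] <- 3L
          }
        }
      }
      arr[, , 1L, f] <- lab
    }
    arr
  }
  lax4 <- lax_label(TRUE)
  lax2 <- lax_label(FALSE)
  # 4CH: in-plane axes x and z, normal +y; 2CH: axes y and z, normal -x
  aff4 <- matrix(0, 4, 4)
  aff4[1, 1] <- h; aff4[3, 2] <- h; aff4[2, 3] <- 1; aff4[4, 4] <- 1
  aff4[1:3, 4] <- c(-half, 0, zg[1])
  aff2 <- matrix(0, 4, 4)
  aff2[2, 1] <- h; aff2[3, 2] <- h; aff2[1, 3] <- -1; aff2[4, 4] <- 1
  aff2[1:3, 4] <- c(0, -half, zg[1])
  lax4_stack <- labelled_stack(lax4, aff4, c(h, h), 6, 0, frame_times, "LAX4CH")
  lax2_stack <- labelled_stack(lax2, aff2, c(h, h), 6, 0, frame_times, "LAX2CH")

  images <- NULL
  if (spec$with_images) {
    set.seed(spec$seed)
    lut <- c(0.15, 1.0, 0.45, 0.9)  # background, LV pool, myocardium, RV pool
    mk <- function(lab) {
      img <- array(lut[lab + 1L], dim = dim(lab))
      img <- img + array(stats::rnorm(length(img), 0, 0.02), dim = dim(img))
      blur_inplane(img)
    }
    images <- list(sax = mk(sax), lax2ch = mk(lax2), lax4ch = mk(lax4))
  }

  study <- cine_study(sax_stack, lax2_stack, lax4_stack,
                      subject = spec$subject, images = images)

  fields <- NULL
  if (spec$with_fields) {
    fields <- list(
      sax = rasterize_field_sax(spec, geo, xg, z_slices),
      lax4ch = rasterize_field_lax(spec, geo, xg, zg, axis = "x"),
      lax2ch = rasterize_field_lax(spec, geo, xg, zg, axis = "y"))
  }

  # analytic LV volume as an ideal slice-summation would see it (exact
  # in-plane areas sampled at the slice centers): the reference for
  # in-plane voxelization error, free of the slice-spacing sampling term
  lv_gridded <- vapply(seq_len(nf), function(f)
    sum(pi * radius_sq_profile(geo$a_pool[f], spec$lv_length, z_slices)) *
      dz / 1000, numeric(1))

  truth <- list(
    tfrac = geo$tfrac,
    frame_times = frame_times,
    lv_volume = geo$v_lv, rv_volume = geo$v_rv,
    lv_volume_gridded = lv_gridded,
    lv_params = analytic_cycle_parameters(spec$lv, spec$rr_interval),
    rv_params = analytic_cycle_parameters(spec$rv, spec$rr_interval),
    lv_wall_volume = spec$lv_wall_volume,
    fields = fields,
    geo = geo)
  structure(list(study = study, truth = truth, spec = spec), class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom: LV EDV %.0f ml / ESV %.0f ml, RV EDV %.0f ml, %d frames>\n",
              x$spec$lv$edv, x$spec$lv$esv, x$spec$rv$edv, x$spec$n_frames))
  invisible(x)
}

# radial material map at height z: ED radius -> frame-f radius
radial_map <- function(spec, geo, z, f, r) {
  re0 <- sqrt(radius_sq_profile(geo$a_pool[1], spec$lv_length, z))
  rp0 <- sqrt(radius_sq_profile(geo$a_epi[1], geo$l_epi, z))
  ret <- sqrt(radius_sq_profile(geo$a_pool[f], spec$lv_length, z))
  rpt <- sqrt(radius_sq_profile(geo$a_epi[f], geo$l_epi, z))
  decay <- 15
  out <- r
  if (rp0 <= 0) return(out)
  if (re0 > 0) {
    pool <- r <= re0
    out[pool] <- r[pool] * (ret / re0)
    wall <- r > re0 & r <= rp0
    out[wall] <- ret + (r[wall] - re0) * (rpt - ret) / (rp0 - re0)
  } else {
    wall <- r <= rp0
    out[wall] <- r[wall] * (rpt / rp0)
  }
  beyond <- r > rp0
  u_epi <- rpt - rp0
  w <- pmax(0, 1 - (r[beyond] - rp0) / decay)
  out[beyond] <- r[beyond] + u_epi * w
  out
}

rasterize_field_sax <- function(spec, geo, xg, z_slices) {
  nx <- length(xg); ns <- length(z_slices); nf <- spec$n_frames
  X <- matrix(xg, nx, nx); Y <- matrix(xg, nx, nx, byrow = TRUE)
  R <- sqrt(X^2 + Y^2)
  fld <- array(0, dim = c(nx, nx, ns, nf, 2))
  for (f in seq_len(nf)) {
    for (s in seq_len(ns)) {
      Rp <- radial_map(spec, geo, z_slices[s], f, R)
      scale <- ifelse(R > 1e-9, Rp / R - 1, 0)
      fld[, , s, f, 1] <- scale * X
      fld[, , s, f, 2] <- scale * Y
    }
  }
  fld
}

rasterize_field_lax <- function(spec, geo, xg, zg, axis) {
  nx <- length(xg); nz <- length(zg); nf <- spec$n_frames
  fld <- array(0, dim = c(nx, nz, 1, nf, 2))
  for (f in seq_len(nf)) {
    for (j in seq_len(nz)) {
      r <- abs(xg)
      rp <- radial_map(spec, geo, zg[j], f, r)
      fld[, j, 1, f, 1] <- sign(xg) * (rp - r)
    }
  }
  fld
}

#' Analytic mid-wall circumferential strain of a phantom
#'
#' Ground-truth per-frame circumferential strain at a given long-axis height:
#' the mid-wall ring radius ratio to ED, minus one, in percent.
#'
#' @param phantom a `phantom`.
#' @param z world height along the long axis, mm (0 = base).
#' @return numeric vector, one strain value (%) per frame.
#' @export
phantom_ecc_curve <- function(phantom, z) {
  geo <- phantom$truth$geo
  spec <- phantom$spec
  r_mid <- function(f) {
    re <- sqrt(radius_sq_profile(geo$a_pool[f], spec$lv_length, z))
    rp <- sqrt(radius_sq_profile(geo$a_epi[f], geo$l_epi, z))
    (re + rp) / 2
  }
  r0 <- r_mid(1)
  vapply(seq_len(spec$n_frames), function(f) 100 * (r_mid(f) / r0 - 1),
         numeric(1))
}

# small separable in-plane blur (5-point binomial), applied per slice/frame
blur_inplane <- function(img) {
  k <- c(1, 4, 6, 4, 1) / 16
  d <- dim(img)
  sm1 <- function(m) {
    out <- m
    for (i in seq_len(nrow(m)))
      out[i, ] <- stats::filter(m[i, ], k, sides = 2, circular = TRUE)
    for (j in seq_len(ncol(m)))
      out[, j] <- stats::filter(out[, j], k, sides = 2, circular = TRUE)
    out
  }
  for (s in seq_len(d[3])) for (f in seq_len(d[4]))
    img[, , s, f] <- sm1(img[, , s, f])
  img
}

# --- artifact injection ---------------------------------------------------

#' Acquisition-artifact specification
#'
#' @param kind one of `missing_basal_slices`, `missing_apical_slices`,
#'   `breathhold_shift`, `off_axis_tilt`, `rv_sv_mismatch`,
#'   `frame_corruption`.
#' @param magnitude slice count (missing slices), mm (breath-hold shift),
#'   degrees (tilt), or fractional SV reduction (RV/LV SV mismatch).
#' @param slice 0-based SAX slice index for `breathhold_shift`.
#' @param direction in-plane unit direction (row, col) for the shift.
#' @param view LAX view to tilt (`"lax4ch"` or `"lax2ch"`).
#' @return object of class `artifact_spec`.
#' @export
artifact_spec <- function(kind, magnitude, slice = NULL,
                          direction = c(1, 0), view = "lax4ch") {
  kind <- match.arg(kind, c("missing_basal_slices", "missing_apical_slices",
                            "breathhold_shift", "off_axis_tilt",
                            "rv_sv_mismatch", "frame_corruption"))
  structure(list(kind = kind, magnitude = magnitude, slice = slice,
                 direction = direction, view = view),
            class = "artifact_spec")
}

drop_slices <- function(stack, keep) {
  if (length(keep) == 0L) stop("cannot remove all slices")
  first_kept <- min(keep)
  aff <- stack$affine
  aff[1:3, 4] <- aff[1:3, 4] + aff[1:3, 3] * (first_kept - 1)
  labelled_stack(stack$labels[, , keep, , drop = FALSE], aff,
                 stack$voxel_size, stack$slice_thickness, stack$slice_gap,
                 stack$frame_times, stack$view)
}

shift_slice_labels <- function(stack, slice0, shift_mm, direction) {
  h <- stack$voxel_size
  dvox <- round(shift_mm * unit(direction) / h)
  lab <- stack$labels
  s <- slice0 + 1L
  d <- dim(lab)
  sl <- lab[, , s, , drop = FALSE]
  out <- array(0L, dim = dim(sl))
  r_src <- seq_len(d[1]) - dvox[1]
  c_src <- seq_len(d[2]) - dvox[2]
  ok_r <- r_src >= 1 & r_src <= d[1]
  ok_c <- c_src >= 1 & c_src <= d[2]
  out[ok_r, ok_c, , ] <- sl[r_src[ok_r], c_src[ok_c], , , drop = FALSE]
  lab[, , s, ] <- out
  stack$labels <- lab
  stack
}

#' Inject an acquisition artifact into a study
#'
#' Produces a corrupted copy of a study for QC and alignment testing. The
#' `rv_sv_mismatch` kind needs the phantom (it rebuilds the RV with a reduced
#' stroke volume); all other kinds operate on the study directly.
#'
#' @param x a `cine_study` or `phantom`.
#' @param art an [artifact_spec()].
#' @param seed integer; drives the random frame choice for
#'   `frame_corruption`.
#' @return same class as `x`, with the artifact applied.
#' @export
inject_artifact <- function(x, art, seed = 1L) {
  is_phantom <- inherits(x, "phantom")
  study <- if (is_phantom) x$study else x
  switch(art$kind,
    missing_basal_slices = {
      k <- as.integer(art$magnitude)
      ns <- n_slices(study$sax)
      if (k >= ns) stop("cannot remove all slices")
      if (k > 0) study$sax <- drop_slices(study$sax, (k + 1L):ns)
    },
    missing_apical_slices = {
      k <- as.integer(art$magnitude)
      ns <- n_slices(study$sax)
      if (k >= ns) stop("cannot remove all slices")
      if (k > 0) study$sax <- drop_slices(study$sax, 1L:(ns - k))
    },
    breathhold_shift = {
      if (is.null(art$slice)) stop("breathhold_shift needs a slice index")
      study$sax <- shift_slice_labels(study$sax, art$slice, art$magnitude,
                                      art$direction)
    },
    off_axis_tilt = {
      st <- study[[art$view]]
      ang <- art$magnitude * pi / 180
      # pivot about the in-plane row axis at the base (z = 0 end)
      e_r <- unit(st$affine[1:3, 1])
      rot <- rotation_about_axis(e_r, ang)
      aff <- st$affine
      pivot <- aff[1:3, 4]
      aff[1:3, 1:3] <- rot %*% aff[1:3, 1:3]
      aff[1:3, 4] <- pivot  # origin (base end) unchanged
      st$affine <- aff
      study[[art$view]] <- st
    },
    rv_sv_mismatch = {
      if (!is_phantom) stop("rv_sv_mismatch requires a phantom")
      spec <- x$spec
      lv_sv <- spec$lv$edv - spec$lv$esv
      new_sv <- lv_sv * (1 - art$magnitude)
      old <- spec$rv
      scale <- new_sv / (old$edv - old$esv)
      spec$rv <- volume_curve_model(
        edv = old$edv, esv = old$edv - new_sv, t_es = old$t_es,
        e_peak_time = old$e_peak_time, a_peak_time = old$a_peak_time,
        wave_widths = old$wave_widths,
        e_wave_amplitude = old$e_wave_amplitude * scale,
        a_wave_amplitude = old$a_wave_amplitude * scale)
      return(build_phantom(spec))
    },
    frame_corruption = {
      set.seed(seed)
      f <- sample(2:n_frames(study$sax), 1L)
      study$sax$labels[, , , f] <- study$sax$labels[, , , f - 1L]
    })
  if (is_phantom) { x$study <- study; x } else study
}

rotation_about_axis <- function(axis, angle) {
  a <- unit(axis); c0 <- cos(angle); s0 <- sin(angle)
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) * c0 + s0 * K + (1 - c0) * (a %o% a)
}

#' Draw a physiologically jittered volume-curve model
#'
#' Samples a [volume_curve_model()] with EDV, EF, phase timings and atrial
#' fraction drawn from physiologic ranges, using the current RNG state.
#'
#' @param edv_range,ef_range sampling ranges for EDV (ml) and EF (fraction).
#' @return a `volume_curve_model`.
#' @export
random_volume_curve_model <- function(edv_range = c(120, 220),
                                      ef_range = c(0.45, 0.7)) {
  edv <- stats::runif(1, edv_range[1], edv_range[2])
  ef <- stats::runif(1, ef_range[1], ef_range[2])
  e_peak <- stats::runif(1, 0.48, 0.56)
  volume_curve_model(edv, edv * (1 - ef),
                     t_es = stats::runif(1, 0.30, e_peak - 0.105),
                     e_peak_time = e_peak,
                     a_peak_time = stats::runif(1, 0.82, 0.88),
                     a_fraction = stats::runif(1, 0.2, 0.4))
}

# --- labelled curve dataset for QC classifier training --------------------

#' Generate a labelled curve dataset for QC classifier training
#'
#' Emulates the curve-shape training corpus for the post-analysis SVMs: "good"
#' exemplars are analytic phantom volume and strain curves under physiologic
#' parameter jitter plus mild measurement noise; "bad" exemplars carry one of
#' four QC-relevant pathologies (cycle non-closure, a single-frame spike,
#' sign-flipped strain, clipped systolic plateau), each labelled with its
#' pathology.
#'
#' @param n_good,n_bad counts per class (each split evenly between volume and
#'   strain curves).
#' @param seed integer seed; the dataset is a pure function of
#'   `(n_good, n_bad, seed)`.
#' @param n_frames samples per curve.
#' @return list with `curves` (list of numeric vectors), `type`
#'   (volume/strain), `label` (good/bad), `pathology`.
#' @export
make_curve_dataset <- function(n_good, n_bad, seed = 1L, n_frames = 50L) {
  if (n_good <= 0) stop("n_good must be positive")
  set.seed(seed)
  tfrac <- (seq_len(n_frames) - 1) / n_frames

  rand_volume_curve <- function() {
    m <- random_volume_curve_model()
    analytic_volume(m, tfrac) + stats::rnorm(n_frames, 0, 0.5)
  }
  rand_strain_curve <- function() {
    peak <- -stats::runif(1, 12, 24)
    tpk <- stats::runif(1, 0.3, 0.4)
    base <- peak * raised_cos_cdf(tfrac, 0, tpk) *
      (1 - raised_cos_cdf(tfrac, stats::runif(1, 0.45, 0.55),
                          stats::runif(1, 0.3, 0.4)))
    base + stats::rnorm(n_frames, 0, 0.15)
  }

  corrupt <- function(curve, type) {
    patho <- sample(c("non_closure", "spike", "sign_flip", "clipped_plateau"), 1L)
    if (type == "volume" && patho == "sign_flip") patho <- "non_closure"
    amp <- diff(range(curve))
    switch(patho,
      non_closure = curve + seq(0, stats::runif(1, 0.2, 0.4) * amp,
                                length.out = length(curve)),
      spike = {
        i <- sample(seq(5, length(curve) - 4), 1L)
        curve[i] <- curve[i] + sample(c(-1, 1), 1) * stats::runif(1, 0.8, 1.2) * amp
        curve
      },
      sign_flip = -curve,
      clipped_plateau = {
        lim <- stats::quantile(curve, 0.75)
        pmin(curve, lim)
      }) -> out
    list(curve = out, pathology = patho)
  }

  curves <- list(); type <- character(0); label <- character(0)
  pathology <- character(0)
  n_gv <- ceiling(n_good / 2); n_gs <- n_good - n_gv
  for (i in seq_len(n_gv)) curves[[length(curves) + 1L]] <- rand_volume_curve()
  type <- c(type, rep("volume", n_gv))
  for (i in seq_len(n_gs)) curves[[length(curves) + 1L]] <- rand_strain_curve()
  type <- c(type, rep("strain", n_gs))
  label <- rep("good", n_good)
  pathology <- rep("none", n_good)
  if (n_bad > 0) {
    n_bv <- ceiling(n_bad / 2); n_bs <- n_bad - n_bv
    for (i in seq_len(n_bv)) {
      cc <- corrupt(rand_volume_curve(), "volume")
      curves[[length(curves) + 1L]] <- cc$curve
      type <- c(type, "volume"); pathology <- c(pathology, cc$pathology)
    }
    for (i in seq_len(n_bs)) {
      cc <- corrupt(rand_strain_curve(), "strain")
      curves[[length(curves) + 1L]] <- cc$curve
      type <- c(type, "strain"); pathology <- c(pathology, cc$pathology)
    }
    label <- c(label, rep("bad", n_bad))
  }
  list(curves = curves, type = type, label = label, pathology = pathology)
}
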