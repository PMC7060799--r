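# Feature-tracking myocardial strain.
#
# End-diastolic contours are sampled from the LV wall segmentation at
# sub-voxel precision (marching-squares level set of the label indicator),
# tracked through the cycle either by advection through supplied displacement
# fields (phantom ground truth or an external registrar) or by a built-in
# demons-style frame-to-frame tracker on intensity images, and converted to
# global Lagrangian strain curves.

# longest contour of indicator >= 0.5 in a 2-D slice; local mm coordinates
# along the row/col axes
level_contour <- function(mask, spacing) {
  x <- (seq_len(nrow(mask)) - 1) * spacing[1]
  y <- (seq_len(ncol(mask)) - 1) * spacing[2]
  cl <- grDevices::contourLines(x, y, mask + 0, levels = 0.5)
  if (length(cl) == 0L) return(NULL)
  lens <- vapply(cl, function(cc) {
    p <- cbind(cc$x, cc$y)
    sum(sqrt(rowSums(diff(p)^2)))
  }, numeric(1))
  cc <- cl[[which.max(lens)]]
  cbind(cc$x, cc$y)
}

# resample a polyline to n points equally spaced by arc length
resample_arclength <- function(pts, n, closed = TRUE) {
  if (closed && any(pts[1, ] != pts[nrow(pts), ])) pts <- rbind(pts, pts[1, ])
  seg <- sqrt(rowSums(diff(pts)^2))
  pts <- pts[c(TRUE, seg > 1e-12), , drop = FALSE]  # drop repeated vertices
  seg <- sqrt(rowSums(diff(pts)^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  target <- if (closed) seq(0, total, length.out = n + 1L)[-(n + 1L)]
  else seq(0, total, length.out = n)
  apply(pts, 2, function(coord) stats::approx(s, coord, xout = target,
                                              rule = 2)$y)
}

# low-pass a closed contour: uniform arc-length resampling at high density,
# Fourier truncation of the complex coordinate, so voxel staircase detail
# does not inflate perimeters
smooth_closed_contour <- function(pts, harmonics = 12L, density = 192L) {
  p <- resample_arclength(pts, density, closed = TRUE)
  z <- complex(real = p[, 1], imaginary = p[, 2])
  co <- stats::fft(z)
  k <- fft_freqs(density)
  co[abs(k) > harmonics] <- 0
  z <- stats::fft(co, inverse = TRUE) / density
  cbind(Re(z), Im(z))
}

# canonical start (angle 0 from centroid) and counterclockwise orientation
canonicalize_closed <- function(pts) {
  ctr <- colMeans(pts)
  ang <- atan2(pts[, 2] - ctr[2], pts[, 1] - ctr[1])
  # signed area for orientation
  i2 <- c(2:nrow(pts), 1)
  area <- sum(pts[, 1] * pts[i2, 2] - pts[i2, 1] * pts[, 2]) / 2
  if (area < 0) { pts <- pts[nrow(pts):1, ]; ang <- ang[length(ang):1] }
  start <- which.min(abs(ang))
  if (start > 1) pts <- rbind(pts[start:nrow(pts), , drop = FALSE],
                              pts[1:(start - 1), , drop = FALSE])
  pts
}

# local in-plane mm -> world, for slice slice0
inplane_to_world <- function(stack, slice0, pts2) {
  e_r <- unit(stack$affine[1:3, 1]); e_c <- unit(stack$affine[1:3, 2])
  org <- world_coords(stack, c(0, 0, slice0))
  t(org + outer(e_r, pts2[, 1]) + outer(e_c, pts2[, 2]))
}

new_tracked_contour <- function(points, kind, source_slice = NA_integer_,
                                closed = TRUE) {
  if (length(dim(points)) == 2L) points <- array(points, c(dim(points), 1L))
  structure(list(points = points, kind = kind, source_slice = source_slice,
                 closed = closed), class = "tracked_contour")
}

#' Sample end-diastolic myocardial contours
#'
#' Selects `n_sax` SAX slices at 25/50/75% of the segmented LV long-axis
#' extent and extracts sub-voxel endocardial and epicardial contours of the
#' LV wall at ED (marching squares on the label indicators), resampled to
#' `n_points` equally spaced by arc length with a canonical start point and
#' orientation; the mid-wall contour is the pointwise endo/epi average. From
#' each LAX view an open mid-myocardial midline is extracted from basal
#' corner around the apex to the other basal corner.
#'
#' @param study a `cine_study`.
#' @param n_sax number of SAX slices (3).
#' @param n_points contour points (default 48).
#' @return list with `sax` (per slice: `endo`, `epi`, `midwall`
#'   `tracked_contour`s and `slice_index`) and `lax` (per view: open midline
#'   `tracked_contour`).
#' @export
sample_ed_contours <- function(study, n_sax = 3L, n_points = 48L) {
  sax <- study$sax
  myo_per_slice <- vapply(seq_len(n_slices(sax)), function(s)
    sum(sax$labels[, , s, 1] == LABEL_LV_MYO), numeric(1))
  with_myo <- which(myo_per_slice > 0)
  if (length(with_myo) < n_sax)
    stop("fewer than ", n_sax, " SAX slices contain myocardium at ED")
  fr <- seq(0.25, 0.75, length.out = n_sax)
  pick <- with_myo[round(stats::quantile(seq_along(with_myo), fr, type = 4))]
  pick <- unique(pick)
  while (length(pick) < n_sax) {  # degenerate few-slice stacks
    extra <- setdiff(with_myo, pick)
    pick <- sort(c(pick, extra[1]))
  }

  sax_contours <- lapply(pick, function(s) {
    lab <- sax$labels[, , s, 1]
    endo2 <- level_contour(lab == LABEL_LV_POOL, sax$voxel_size)
    epi2 <- level_contour(lab == LABEL_LV_POOL | lab == LABEL_LV_MYO,
                          sax$voxel_size)
    if (is.null(endo2) || is.null(epi2))
      stop("could not extract wall contours on slice ", s - 1L)
    endo2 <- resample_arclength(
      canonicalize_closed(smooth_closed_contour(endo2)), n_points)
    epi2 <- resample_arclength(
      canonicalize_closed(smooth_closed_contour(epi2)), n_points)
    endo <- inplane_to_world(sax, s - 1L, endo2)
    epi <- inplane_to_world(sax, s - 1L, epi2)
    list(endo = new_tracked_contour(endo, "endo", s - 1L),
         epi = new_tracked_contour(epi, "epi", s - 1L),
         midwall = new_tracked_contour((endo + epi) / 2, "midwall", s - 1L),
         slice_index = s - 1L)
  })

  lax_contours <- lapply(c(lax2ch = "lax2ch", lax4ch = "lax4ch"), function(k) {
    st <- study[[k]]
    lab <- st$labels[, , 1, 1]
    midline2 <- lax_midline(lab, st$voxel_size, n_points)
    if (is.null(midline2)) stop("could not extract LAX midline in ", k)
    pts <- inplane_to_world(st, 0L, midline2)
    new_tracked_contour(pts, "lax_midline", 0L, closed = FALSE)
  })

  list(sax = sax_contours, lax = lax_contours, n_points = n_points)
}

# open mid-myocardial polyline in a LAX slice: angular sweep of wall pixels
# about the pool centroid, base opening excluded
lax_midline <- function(lab, spacing, n_points, base_exclusion = 0.35) {
  myo <- which(lab == LABEL_LV_MYO, arr.ind = TRUE)
  pool <- which(lab == LABEL_LV_POOL, arr.ind = TRUE)
  if (nrow(myo) < 10 || nrow(pool) < 10) return(NULL)
  mm <- cbind((myo[, 1] - 1) * spacing[1], (myo[, 2] - 1) * spacing[2])
  ctr <- c(mean((pool[, 1] - 1) * spacing[1]), mean((pool[, 2] - 1) * spacing[2]))
  # apex direction: from base (col ~ 0) toward increasing col (long axis)
  ang <- atan2(mm[, 1] - ctr[1], mm[, 2] - ctr[2])  # 0 = apex direction
  keep <- abs(ang) <= pi - base_exclusion
  if (sum(keep) < 10) return(NULL)
  mm <- mm[keep, , drop = FALSE]; ang <- ang[keep]
  breaks <- seq(-(pi - base_exclusion), pi - base_exclusion, length.out = 49L)
  bin <- cut(ang, breaks, include.lowest = TRUE)
  cx <- tapply(mm[, 1], bin, mean); cy <- tapply(mm[, 2], bin, mean)
  ok <- !is.na(cx)
  pts <- cbind(cx[ok], cy[ok])
  resample_arclength(pts, n_points, closed = FALSE)
}

# bilinear sampling of a 2-D matrix at continuous 1-based (r, c)
bilinear <- function(m, r, c) {
  r <- pmin(pmax(r, 1), nrow(m)); c <- pmin(pmax(c, 1), ncol(m))
  r0 <- pmin(floor(r), nrow(m) - 1L); c0 <- pmin(floor(c), ncol(m) - 1L)
  fr <- r - r0; fc <- c - c0
  m[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    m[cbind(r0 + 1, c0)] * fr * (1 - fc) +
    m[cbind(r0, c0 + 1)] * (1 - fr) * fc +
    m[cbind(r0 + 1, c0 + 1)] * fr * fc
}

#' Track contour points through the cycle via displacement fields
#'
#' Advects ED points by sampling, with bilinear interpolation, the frame-t
#' displacement field (which maps ED positions to frame-t positions, in mm
#' along the stack's in-plane row/col axes).
#'
#' @param contour a `tracked_contour` holding ED points (frame 1).
#' @param stack the `labelled_stack` the field is defined on.
#' @param field array `(rows, cols, slices, frames, 2)` of in-plane
#'   displacements in mm.
#' @return the contour with points for every frame.
#' @export
track_with_field <- function(contour, stack, field) {
  pts0 <- matrix(contour$points[, , 1], ncol = 3)
  v <- voxel_coords(stack, pts0)
  d <- dim(stack$labels)
  if (any(v[, 1] < -0.5 | v[, 1] > d[1] - 0.5 |
          v[, 2] < -0.5 | v[, 2] > d[2] - 0.5)) {
    bad <- which(v[, 1] < -0.5 | v[, 1] > d[1] - 0.5 |
                 v[, 2] < -0.5 | v[, 2] > d[2] - 0.5)
    stop("points outside field of view: ", paste(bad, collapse = ", "))
  }
  s <- round(v[1, 3]) + 1L
  nf <- dim(field)[4]
  e_r <- unit(stack$affine[1:3, 1]); e_c <- unit(stack$affine[1:3, 2])
  out <- array(NA_real_, c(nrow(pts0), 3, nf))
  for (f in seq_len(nf)) {
    ur <- bilinear(field[, , s, f, 1], v[, 1] + 1, v[, 2] + 1)
    uc <- bilinear(field[, , s, f, 2], v[, 1] + 1, v[, 2] + 1)
    out[, , f] <- pts0 + outer(ur, e_r) + outer(uc, e_c)
  }
  contour$points <- out
  contour
}

#' Track all sampled contours
#'
#' @param contours output of [sample_ed_contours()].
#' @param study the `cine_study`.
#' @param fields named list of displacement-field arrays (`sax`, `lax2ch`,
#'   `lax4ch`) as produced by the phantom or an external registrar; required
#'   for `method = "fields"`.
#' @param method `"fields"` or `"demons"` (built-in intensity tracker; the
#'   study must carry images).
#' @param ... passed to the demons tracker.
#' @return the contour set with all frames tracked.
#' @export
track_contours <- function(contours, study, fields = NULL,
                           method = c("fields", "demons"), ...) {
  method <- match.arg(method)
  if (method == "fields") {
    if (is.null(fields)) stop("method 'fields' requires displacement fields")
    get_fields <- function(view) fields[[view]]
  } else {
    if (is.null(study$images)) stop("method 'demons' requires intensity images")
    cache <- list()
    get_fields <- function(view) {
      if (is.null(cache[[view]])) {
        st <- study[[view]]
        slices_needed <- if (view == "sax")
          vapply(contours$sax, `[[`, integer(1), "slice_index") else 0L
        cache[[view]] <<- demons_track_fields(study$images[[view]], st,
                                              slices_needed, ...)
      }
      cache[[view]]
    }
  }
  contours$sax <- lapply(contours$sax, function(sl) {
    fld <- get_fields("sax")
    sl$endo <- track_with_field(sl$endo, study$sax, fld)
    sl$epi <- track_with_field(sl$epi, study$sax, fld)
    sl$midwall <- track_with_field(sl$midwall, study$sax, fld)
    sl
  })
  for (k in names(contours$lax))
    contours$lax[[k]] <- track_with_field(contours$lax[[k]], study[[k]],
                                          get_fields(k))
  contours
}

# --- built-in demons-style tracker ---------------------------------------

gaussian_blur2d <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(2 * sigma))
  k <- exp(-(-r:r)^2 / (2 * sigma^2)); k <- k / sum(k)
  out <- apply(m, 2, function(col) stats::filter(col, k, circular = TRUE))
  t(apply(t(out), 2, function(row) stats::filter(row, k, circular = TRUE)))
}

gradient2d <- function(m) {
  gx <- (rbind(m[-1, ], m[nrow(m), ]) - rbind(m[1, ], m[-nrow(m), ])) / 2
  gy <- (cbind(m[, -1], m[, ncol(m)]) - cbind(m[, 1], m[, -ncol(m)])) / 2
  list(gx = gx, gy = gy)
}

# one-level demons registration: returns displacement (voxels) mapping
# fixed-frame coordinates to moving-frame coordinates
demons2d <- function(fixed, moving, n_iter = 30L, sigma_fluid = 1,
                     sigma_field = 1.5) {
  ur <- matrix(0, nrow(fixed), ncol(fixed))
  uc <- matrix(0, nrow(fixed), ncol(fixed))
  rr <- matrix(seq_len(nrow(fixed)), nrow(fixed), ncol(fixed))
  cc <- matrix(seq_len(ncol(fixed)), nrow(fixed), ncol(fixed), byrow = TRUE)
  g <- gradient2d(fixed)
  for (i in seq_len(n_iter)) {
    w <- matrix(bilinear(moving, as.vector(rr + ur), as.vector(cc + uc)),
                nrow(fixed))
    diffi <- w - fixed
    den <- g$gx^2 + g$gy^2 + diffi^2 + 1e-6
    fr <- gaussian_blur2d(-diffi * g$gx / den, sigma_fluid)
    fc <- gaussian_blur2d(-diffi * g$gy / den, sigma_fluid)
    ur <- gaussian_blur2d(ur + fr, sigma_field)
    uc <- gaussian_blur2d(uc + fc, sigma_field)
  }
  list(ur = ur, uc = uc)
}

# compose frame-to-frame demons registrations into ED -> t fields (mm) on
# the slices requested
demons_track_fields <- function(images, stack, slices0, n_iter = 30L, ...) {
  d <- dim(stack$labels)
  nf <- d[4]
  fld <- array(0, c(d[1], d[2], d[3], nf, 2))
  h <- stack$voxel_size
  for (s0 in slices0) {
    s <- s0 + 1L
    # cumulative positions of the ED grid
    rr <- matrix(seq_len(d[1]), d[1], d[2])
    cc <- matrix(seq_len(d[2]), d[1], d[2], byrow = TRUE)
    pr <- rr; pc <- cc
    for (f in 2:nf) {
      u <- demons2d(images[, , s, f - 1], images[, , s, f], n_iter = n_iter, ...)
      # advance tracked positions by the f-1 -> f field
      dur <- matrix(bilinear(u$ur, as.vector(pr), as.vector(pc)), d[1])
      duc <- matrix(bilinear(u$uc, as.vector(pr), as.vector(pc)), d[1])
      pr <- pr + dur; pc <- pc + duc
      fld[, , s, f, 1] <- (pr - rr) * h[1]
      fld[, , s, f, 2] <- (pc - cc) * h[2]
    }
  }
  fld
}

# --- strain curves --------------------------------------------------------

polyline_length <- function(pts, closed) {
  p <- if (closed) rbind(pts, pts[1, ]) else pts
  sum(sqrt(rowSums(diff(p)^2)))
}

#' Global strain curves from tracked contours
#'
#' Lagrangian strain relative to ED (frame 1):
#' circumferential = mid-wall perimeter change averaged over the 3 SAX
#' slices; radial = mean endo-epi thickness change averaged over slices;
#' longitudinal = LAX midline arc-length change, per view. Peaks are the
#' signed extrema (minimum for circumferential/longitudinal, maximum for
#' radial); times-to-peak are in ms from ED.
#'
#' @param contours tracked contour set from [track_contours()].
#' @param frame_times frame times in seconds.
#' @return object of class `strain_report` with per-frame `ecc`, `err`,
#'   `ell_2ch`, `ell_4ch` (%), `peaks` and `tpk_ms`.
#' @export
strain_curves <- function(contours, frame_times) {
  nf <- dim(contours$sax[[1]]$midwall$points)[3]
  per_slice <- function(sl) {
    mid <- sl$midwall$points
    p0 <- polyline_length(mid[, , 1], TRUE)
    if (p0 < 10) stop("degenerate contour (perimeter < 10 mm)")
    perim <- vapply(seq_len(nf), function(f)
      polyline_length(mid[, , f], TRUE), numeric(1))
    th <- vapply(seq_len(nf), function(f)
      mean(sqrt(rowSums((sl$endo$points[, , f] - sl$epi$points[, , f])^2))),
      numeric(1))
    list(ecc = 100 * (perim / p0 - 1), err = 100 * (th / th[1] - 1))
  }
  per <- lapply(contours$sax, per_slice)
  ecc <- rowMeans(vapply(per, `[[`, numeric(nf), "ecc"))
  err <- rowMeans(vapply(per, `[[`, numeric(nf), "err"))
  ell <- lapply(contours$lax, function(tc) {
    l0 <- polyline_length(tc$points[, , 1], FALSE)
    if (l0 < 10) stop("degenerate contour (perimeter < 10 mm)")
    vapply(seq_len(nf), function(f)
      100 * (polyline_length(tc$points[, , f], FALSE) / l0 - 1), numeric(1))
  })
  tpk <- function(curve, minimum = TRUE) {
    i <- if (minimum) which.min(curve) else which.max(curve)
    1000 * frame_times[i]
  }
  structure(list(
    ecc = ecc, err = err,
    ell_2ch = ell$lax2ch, ell_4ch = ell$lax4ch,
    peaks = list(ecc = min(ecc), err = max(err),
                 ell_2ch = min(ell$lax2ch), ell_4ch = min(ell$lax4ch)),
    tpk_ms = list(ecc = tpk(ecc), err = tpk(err, FALSE),
                  ell_2ch = tpk(ell$lax2ch), ell_4ch = tpk(ell$lax4ch)),
    frame_times = frame_times), class = "strain_report")
}

#' @export
print.strain_report <- function(x, ...) {
  cat(sprintf(
    "<strain_report: peak ecc %.1f%%, err %.1f%%, ell 2CH %.1f%% / 4CH %.1f%%>\n",
    x$peaks$ecc, x$peaks$err, x$peaks$ell_2ch, x$peaks$ell_4ch))
  invisible(x)
}

#' Flatten a strain report to a one-row data frame
#' @param report a `strain_report`.
#' @return one-row `data.frame` with peak strains (%) and times to peak (ms).
#' @export
as.data.frame.strain_report <- function(x, ...) {
  data.frame(ecc_pct = x$peaks$ecc, err_pct = x$peaks$err,
             ell_2ch_pct = x$peaks$ell_2ch, ell_4ch_pct = x$peaks$ell_4ch,
             tpk_ecc_ms = x$tpk_ms$ecc, tpk_err_ms = x$tpk_ms$err,
             tpk_ell_2ch_ms = x$tpk_ms$ell_2ch,
             tpk_ell_4ch_ms = x$tpk_ms$ell_4ch)
}
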