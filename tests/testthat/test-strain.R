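# Contour sampling, tracking, and Lagrangian strain.

# hand-built contour set: three circular SAX rings (radius r_mid, wall
# half-thickness w) and two straight LAX midlines, deformed per frame by the
# supplied radial scale factors
make_ring_contours <- function(scales, n_points = 48, r_mid = 30, w = 5,
                               line_len = 80) {
  th <- 2 * pi * (0:(n_points - 1)) / n_points
  nf <- length(scales)
  ring <- function(r) {
    arr <- array(0, c(n_points, 3, nf))
    for (f in seq_len(nf))
      arr[, , f] <- cbind(r * scales[f] * cos(th), r * scales[f] * sin(th), 0)
    arr
  }
  mkc <- function(arr, kind, closed = TRUE)
    structure(list(points = arr, kind = kind, source_slice = 0L,
                   closed = closed), class = "tracked_contour")
  sl <- list(endo = mkc(ring(r_mid - w), "endo"),
             epi = mkc(ring(r_mid + w), "epi"),
             midwall = mkc(ring(r_mid), "midwall"), slice_index = 0L)
  line <- array(0, c(n_points, 3, nf))
  for (f in seq_len(nf))
    line[, , f] <- cbind(seq(0, line_len, length.out = n_points) * scales[f],
                         0, seq(0, 40, length.out = n_points) * scales[f])
  lax <- mkc(line, "lax_midline", closed = FALSE)
  list(sax = list(sl, sl, sl), lax = list(lax2ch = lax, lax4ch = lax),
       n_points = n_points)
}

test_that("phantom contours have the documented shape and uniform arc-length spacing", {
  ph <- field_phantom()
  co <- sample_ed_contours(ph$study)
  expect_length(co$sax, 3L)
  expect_length(co$lax, 2L)
  for (sl in co$sax) {
    for (kind in c("endo", "epi", "midwall")) {
      pts <- sl[[kind]]$points[, , 1]
      expect_equal(nrow(pts), 48L)
      seg <- sqrt(rowSums((pts[c(2:48, 1), ] - pts)^2))
      expect_lt(max(abs(seg / mean(seg) - 1)), 0.05)
    }
  }
  for (tc in co$lax) expect_false(tc$closed)
})

test_that("midwall radius matches the analytic endo/epi average", {
  ph <- field_phantom()
  co <- sample_ed_contours(ph$study)
  geo <- ph$truth$geo
  for (sl in co$sax) {
    z <- (sl$slice_index) * 10 + 5
    re <- sqrt(geo$a_pool[1]^2 * (1 - (z / ph$spec$lv_length)^2))
    rp <- sqrt(geo$a_epi[1]^2 * (1 - (z / geo$l_epi)^2))
    mid <- sl$midwall$points[, , 1]
    r_obs <- mean(sqrt(mid[, 1]^2 + mid[, 2]^2))
    expect_lt(abs(r_obs - (re + rp) / 2), 0.5)
  }
})

test_that("tracking through a zero field is constant and a uniform field is exact", {
  ph <- field_phantom()
  co <- sample_ed_contours(ph$study)
  st <- ph$study$sax
  d <- dim(st$labels)
  zero <- array(0, c(d[1], d[2], d[3], d[4], 2))
  tc <- track_with_field(co$sax[[2]]$midwall, st, zero)
  for (f in 2:d[4]) expect_equal(tc$points[, , f], tc$points[, , 1])

  uni <- zero; uni[, , , , 1] <- 3.5; uni[, , , , 2] <- -2
  tc2 <- track_with_field(co$sax[[2]]$midwall, st, uni)
  e_r <- st$affine[1:3, 1] / sqrt(sum(st$affine[1:3, 1]^2))
  e_c <- st$affine[1:3, 2] / sqrt(sum(st$affine[1:3, 2]^2))
  shift <- 3.5 * e_r - 2 * e_c
  ed_pts <- co$sax[[2]]$midwall$points[, , 1]
  for (f in seq_len(d[4]))
    expect_equal(tc2$points[, , f],
                 ed_pts + matrix(shift, 48, 3, byrow = TRUE),
                 tolerance = 1e-9)

  expect_error(track_with_field(
    structure(list(points = array(c(1e6, 1e6, 0), c(1, 3, 1))),
              class = "tracked_contour"), st, zero),
    "outside field of view")
})

test_that("strain is zero at ED, scales with ring radius, and radial thickening is positive", {
  scales <- c(1, 0.95, 0.8, 0.9, 1)
  sr <- strain_curves(make_ring_contours(scales), frame_times = (0:4) / 5)
  expect_identical(sr$ecc[1], 0)
  expect_identical(sr$err[1], 0)
  expect_identical(sr$ell_2ch[1], 0)
  expect_equal(sr$peaks$ecc, -20, tolerance = 1e-9)   # perimeter ~ radius
  expect_equal(sr$peaks$ell_2ch, -20, tolerance = 1e-9)
  expect_equal(sr$tpk_ms$ecc, 1000 * 2 / 5)

  # incompressible thick ring: inner radius shrink forces wall thickening
  ph <- field_phantom()
  co <- sample_ed_contours(ph$study)
  tr <- track_contours(co, ph$study, fields = ph$truth$fields)
  srp <- strain_curves(tr, ph$study$sax$frame_times)
  expect_gt(srp$peaks$err, 0)
})

test_that("strain is invariant under rigid rotation plus translation of every frame", {
  scales <- c(1, 0.9, 0.85, 0.95, 1)
  co <- make_ring_contours(scales)
  sr0 <- strain_curves(co, (0:4) / 5)
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
              byrow = TRUE)
  tr_vec <- c(12, -4, 9)
  rigid <- function(tc) {
    for (f in seq_len(dim(tc$points)[3]))
      tc$points[, , f] <- tc$points[, , f] %*% t(R) +
        matrix(tr_vec, nrow(tc$points), 3, byrow = TRUE)
    tc
  }
  co$sax <- lapply(co$sax, function(sl) {
    sl$endo <- rigid(sl$endo); sl$epi <- rigid(sl$epi)
    sl$midwall <- rigid(sl$midwall); sl
  })
  co$lax <- lapply(co$lax, rigid)
  sr1 <- strain_curves(co, (0:4) / 5)
  expect_equal(sr1$ecc, sr0$ecc, tolerance = 1e-10)
  expect_equal(sr1$err, sr0$err, tolerance = 1e-10)
  expect_equal(sr1$ell_2ch, sr0$ell_2ch, tolerance = 1e-10)
})

test_that("phantom circumferential strain is recovered within 1% strain from ground-truth fields", {
  ph <- field_phantom()
  co <- sample_ed_contours(ph$study)
  tr <- track_contours(co, ph$study, fields = ph$truth$fields)
  sr <- strain_curves(tr, ph$study$sax$frame_times)
  zs <- vapply(co$sax, function(s) s$slice_index * 10 + 5, numeric(1))
  ecc_true <- rowMeans(vapply(zs, function(z) phantom_ecc_curve(ph, z),
                              numeric(ph$spec$n_frames)))
  expect_lt(max(abs(sr$ecc - ecc_true)), 1)
  expect_lt(abs(sr$peaks$ecc - min(ecc_true)), 1)
})

test_that("perimeter-strain discretization error shrinks as contour points double", {
  # non-circular ring under an anisotropic stretch, tracked analytically:
  # the polygon-perimeter estimate converges to the true perimeter ratio
  a <- 30; b <- 18
  stretch <- c(0.8, 0.9)
  true_ratio <- function(sx, sy) {
    per <- function(ax, by) {
      th <- seq(0, 2 * pi, length.out = 20001)
      sum(sqrt((diff(ax * cos(th)))^2 + (diff(by * sin(th)))^2))
    }
    per(a * sx, b * sy) / per(a, b)
  }
  target <- 100 * (true_ratio(stretch[1], stretch[2]) - 1)
  errs <- vapply(c(12, 24, 48), function(np) {
    th <- 2 * pi * (0:(np - 1)) / np
    p0 <- cbind(a * cos(th), b * sin(th), 0)
    p1 <- cbind(stretch[1] * a * cos(th), stretch[2] * b * sin(th), 0)
    perim <- function(p) sum(sqrt(rowSums((p[c(2:np, 1), ] - p)^2)))
    abs(100 * (perim(p1) / perim(p0) - 1) - target)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("the built-in demons tracker reproduces field-based strain on a small phantom", {
  ph <- cached("demons", function()
    build_phantom(phantom_spec(voxel_size = 3, n_frames = 12,
                               with_fields = TRUE, with_images = TRUE)))
  co <- sample_ed_contours(ph$study)
  trf <- track_contours(co, ph$study, fields = ph$truth$fields)
  srf <- strain_curves(trf, ph$study$sax$frame_times)
  trd <- track_contours(co, ph$study, method = "demons", n_iter = 15L)
  srd <- strain_curves(trd, ph$study$sax$frame_times)
  expect_lt(abs(srd$peaks$ecc - srf$peaks$ecc), 5)
  expect_equal(sign(srd$peaks$ecc), -1)
})
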