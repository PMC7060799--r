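# Phantom generator: analytic curve model, voxelization accuracy, artifact
# injection, curve dataset.

test_that("analytic volume curve hits its landmarks and conserves volume over a cycle", {
  m <- volume_curve_model(179, 77)
  expect_equal(analytic_volume(m, 0), 179)
  expect_equal(analytic_volume(m, m$t_es), 77, tolerance = 1e-9)
  expect_equal(analytic_volume(m, 1), 179, tolerance = 1e-9)
  # quadrature oracle: the rate integrates to zero over the cycle
  net <- stats::integrate(function(t) analytic_dvdt(m, t), 0, 1,
                          subdivisions = 2000L, rel.tol = 1e-10)$value
  expect_lt(abs(net), 1e-6)
  expect_error(volume_curve_model(77, 179), "edv > esv")
  expect_error(volume_curve_model(179, 77, e_wave_amplitude = 50,
                                  a_wave_amplitude = 20),
               "sum to the stroke volume")
})

test_that("closed-form cycle parameters match a fine-grid numerical oracle", {
  set.seed(4)
  for (i in 1:5) {
    m <- random_volume_curve_model()
    cf <- analytic_cycle_parameters(m, rr_interval = 1)
    tt <- seq(0, 1, length.out = 20001)
    dv <- analytic_dvdt(m, tt)
    expect_equal(cf$per, max(-dv), tolerance = 1e-4)
    dia <- tt > m$t_es
    expect_equal(cf$pefr, max(dv[dia & tt < 0.7]), tolerance = 1e-4)
    expect_equal(cf$pafr, max(dv[tt > 0.7]), tolerance = 1e-4)
    # AC oracle: volume gained after the diastasis plateau
    v <- analytic_volume(m, tt)
    i_dia <- which(tt > m$e_peak_time + m$wave_widths[1] / 2 &
                   tt < m$a_peak_time - m$wave_widths[2] / 2)[1]
    expect_equal(cf$ac_ml, v[length(v)] - v[i_dia], tolerance = 1e-6)
  }
})

test_that("voxelized LV pool volume matches the analytic ellipsoid volume within 1% at 1 mm", {
  ph <- build_phantom(phantom_spec(lv = volume_curve_model(179, 77),
                                   voxel_size = 1, n_frames = 4))
  for (f in 1:4) {
    v <- slice_summation_volume(ph$study$sax, 1L, f)
    expect_lt(abs(v - ph$truth$lv_volume[f]) / ph$truth$lv_volume[f], 0.01)
  }
  # myocardial shell volume is conserved within 2%
  wall <- slice_summation_volume(ph$study$sax, 2L, 1L)
  expect_lt(abs(wall - ph$spec$lv_wall_volume) / ph$spec$lv_wall_volume, 0.02)
})

test_that("voxelization error vs the slice-sampled analytic volume is non-increasing under voxel halving", {
  set.seed(7)
  models <- lapply(1:3, function(i) random_volume_curve_model())
  errs <- vapply(c(2, 1, 0.5), function(h) {
    mean(vapply(models, function(lv) {
      ph <- build_phantom(phantom_spec(lv = lv, voxel_size = h, n_frames = 3))
      v <- vapply(1:3, function(f)
        slice_summation_volume(ph$study$sax, 1L, f), numeric(1))
      mean(abs(v - ph$truth$lv_volume_gridded[1:3]) /
             ph$truth$lv_volume_gridded[1:3])
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-12))
})

test_that("near-zero-amplitude motion yields near-zero displacement fields", {
  m <- volume_curve_model(150, 149.8, e_wave_amplitude = 0.1,
                          a_wave_amplitude = 0.1)
  ph <- build_phantom(phantom_spec(lv = m, rv = volume_curve_model(150, 149.8,
                                   e_wave_amplitude = 0.1,
                                   a_wave_amplitude = 0.1),
                                   voxel_size = 3, n_frames = 10,
                                   with_fields = TRUE))
  expect_lt(max(abs(ph$truth$fields$sax)), 0.05)
  # fields are exactly zero at the ED frame (cycle consistency)
  expect_true(all(ph$truth$fields$sax[, , , 1, ] == 0))
})

test_that("phantom output is a pure function of spec and seed", {
  spec <- phantom_spec(voxel_size = 3, n_frames = 8, with_images = TRUE,
                       seed = 42)
  a <- build_phantom(spec)
  b <- build_phantom(spec)
  expect_identical(a$study$sax$labels, b$study$sax$labels)
  expect_identical(a$images, b$images)
  expect_identical(a$truth$lv_volume, b$truth$lv_volume)
})

test_that("RV stroke-volume mismatch injection rescales the measured SV ratio", {
  ph <- coarse_phantom()
  mism <- inject_artifact(ph, artifact_spec("rv_sv_mismatch", 0.2))
  lv_sv <- diff(range(-sapply(1:20, function(f)
    slice_summation_volume(mism$study$sax, 1L, f))))
  rv_sv <- diff(range(-sapply(1:20, function(f)
    slice_summation_volume(mism$study$sax, 3L, f))))
  expect_equal(rv_sv / lv_sv, 0.8, tolerance = 0.02)
})

test_that("slice-removal artifacts drop slices and guard against emptying the stack", {
  ph <- coarse_phantom()
  same <- inject_artifact(ph$study, artifact_spec("missing_basal_slices", 0))
  expect_identical(same$sax$labels, ph$study$sax$labels)
  ns <- dim(ph$study$sax$labels)[3]
  less <- inject_artifact(ph$study, artifact_spec("missing_basal_slices", 2))
  expect_equal(dim(less$sax$labels)[3], ns - 2L)
  # remaining slice planes keep their world positions
  expect_equal(plane_of(less$sax, 0L)$origin, plane_of(ph$study$sax, 2L)$origin)
  expect_error(inject_artifact(ph$study,
                               artifact_spec("missing_basal_slices", ns)),
               "cannot remove all slices")
})

test_that("frame corruption copies the previous frame deterministically", {
  ph <- coarse_phantom()
  a <- inject_artifact(ph$study, artifact_spec("frame_corruption", 1), seed = 5)
  b <- inject_artifact(ph$study, artifact_spec("frame_corruption", 1), seed = 5)
  expect_identical(a$sax$labels, b$sax$labels)
  changed <- which(vapply(seq_len(20), function(f)
    !identical(a$sax$labels[, , , f], ph$study$sax$labels[, , , f]),
    logical(1)))
  expect_length(changed, 1L)
  expect_identical(a$sax$labels[, , , changed],
                   a$sax$labels[, , , changed - 1L])
})

test_that("curve dataset labels, pathologies and determinism behave as documented", {
  all_good <- make_curve_dataset(10, 0, seed = 1)
  expect_true(all(all_good$label == "good"))

  a <- make_curve_dataset(20, 15, seed = 9)
  b <- make_curve_dataset(20, 15, seed = 9)
  expect_identical(a, b)
  expect_equal(sum(a$label == "bad"), 15L)
  expect_true(all(a$pathology[a$label == "bad"] != "none"))

  # spike pathology: exactly one frame deviating more than 5 SD from the
  # local trend. Standard despike-validate oracle: locate the suspect frame,
  # interpolate it away, and measure every frame against the leave-one-out
  # trend of the cleaned curve.
  spikes <- which(a$pathology == "spike")
  for (i in spikes) {
    x <- a$curves[[i]]
    n <- length(x)
    imax <- which.max(abs(x - stats::runmed(x, 7)))
    xc <- x
    xc[imax] <- (x[imax - 1] + x[imax + 1]) / 2
    resid <- x[2:(n - 1)] - (xc[1:(n - 2)] + xc[3:n]) / 2
    s <- stats::sd(resid[-(imax - 1)])
    expect_equal(sum(abs(resid) > 5 * s), 1L)
  }
})
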