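# Post-analysis QC rules, curve features, SVM classifiers, verdict logic.

fake_report <- function(sv, edv = 160) {
  structure(list(chamber = "LV", edv = edv, esv = edv - sv, sv = sv,
                 ef = 100 * sv / edv), class = "volumetry_report")
}

flat_curve <- function(v0, vlast = v0, n = 30) {
  v <- rep(v0, n); v[n] <- vlast
  volume_curve_from_values(v, (0:(n - 1)) / n)
}

test_that("SV-difference and closure rules apply the 10% thresholds", {
  ok <- check_output_rules(fake_report(100), fake_report(95),
                           flat_curve(150), flat_curve(150))
  expect_equal(ok$sv_difference$status, "pass")
  expect_equal(ok$sv_difference$measured_value, 5 / 97.5, tolerance = 1e-9)

  bad <- check_output_rules(fake_report(100), fake_report(80),
                            flat_curve(150), flat_curve(150))
  expect_equal(bad$sv_difference$status, "flag")
  expect_equal(bad$sv_difference$measured_value, 20 / 90, tolerance = 1e-9)

  cl <- check_output_rules(fake_report(100), fake_report(98),
                           flat_curve(150, 130), flat_curve(140))
  expect_equal(cl$closure$status, "flag")
  expect_equal(cl$closure$measured_value, 20 / 150, tolerance = 1e-9)

  degen <- check_output_rules(fake_report(1e-9), fake_report(-1e-9, edv = 160),
                              flat_curve(150), flat_curve(150))
  expect_equal(degen$sv_difference$status, "flag")
  expect_match(degen$sv_difference$message, "degenerate SV")
})

test_that("plane-consistency rules pass on an intact phantom and catch constructed violations", {
  ph <- coarse_phantom()
  res <- check_plane_consistency(ph$study)
  for (r in res) expect_equal(r$status, "pass")
  expect_gte(res$missing_slice$measured_value, 0.95)
  expect_gte(res$coverage$measured_value, 0.95)

  miss <- inject_artifact(ph$study, artifact_spec("missing_basal_slices", 2))
  expect_equal(check_plane_consistency(miss)$missing_slice$status, "flag")

  tilt <- inject_artifact(ph$study, artifact_spec("off_axis_tilt", 25))
  expect_equal(check_plane_consistency(tilt)$intersection$status, "flag")
})

test_that("curve features are scale invariant, shift covariant and spike sensitive", {
  set.seed(21)
  m <- random_volume_curve_model()
  v <- analytic_volume(m, (0:63) / 64)
  f1 <- curve_features(v)
  f2 <- curve_features(v * 2)
  expect_equal(f2[1:32], f1[1:32], tolerance = 1e-12)

  shifted <- c(v[17:64], v[1:16])  # cyclic shift by a quarter cycle
  fs <- curve_features(shifted)
  expect_equal(unname(fs[1:32]),
               unname(f1[1:32][c(9:32, 1:8)]), tolerance = 1e-9)

  spiked <- v; spiked[30] <- spiked[30] + 3 * diff(range(v))
  expect_gt(curve_features(spiked)[["max_jump"]], 3 * f1[["max_jump"]])

  const <- curve_features(rep(5, 30))
  expect_true(all(is.finite(const)))
})

test_that("the QC SVM separates a separable toy set perfectly and deterministically", {
  n <- 40
  tt <- (0:29) / 30
  curves <- c(lapply(seq_len(n), function(i) sin(2 * pi * tt) * (1 + i / n)),
              lapply(seq_len(n), function(i) {
                x <- sin(2 * pi * tt) * (1 + i / n)
                x + seq(0, 3, length.out = 30)  # gross drift
              }))
  ds <- list(curves = curves, type = rep("volume", 2 * n),
             label = rep(c("good", "bad"), each = n),
             pathology = rep(c("none", "non_closure"), each = n))
  fit <- train_qc_svm(ds, "volume", seed = 3)
  expect_equal(fit$cv_bacc, 1.0)

  fit2 <- train_qc_svm(ds, "volume", seed = 3)
  preds1 <- vapply(curves, function(cu) predict_qc_svm(fit, cu)$label, "")
  preds2 <- vapply(curves, function(cu) predict_qc_svm(fit2, cu)$label, "")
  expect_identical(preds1, preds2)

  single <- ds; single$label <- rep("good", 2 * n)
  expect_error(train_qc_svm(single, "volume"), "both classes")
})

test_that("trained classifiers survive a save/load round trip", {
  ds <- make_curve_dataset(60, 40, seed = 31)
  fit <- train_qc_svm(ds, "volume", seed = 31)
  f <- withr::local_tempfile(fileext = ".rds")
  save_qc_svm(fit, f)
  fit2 <- load_qc_svm(f)
  p1 <- lapply(ds$curves[1:10], function(cu) predict_qc_svm(fit, cu))
  p2 <- lapply(ds$curves[1:10], function(cu) predict_qc_svm(fit2, cu))
  expect_identical(p1, p2)
})

test_that("the verdict flags iff a rule flags or an SVM is anomalous, monotonically", {
  pass_rule <- function(id) cinemetrics:::qc_rule_result(id, "pass", 0.5, 1)
  flag_rule <- function(id) cinemetrics:::qc_rule_result(id, "flag", 2, 1, "boom")
  good_svm <- list(label = "good", margin = -1)
  bad_svm <- list(label = "anomalous", margin = 1)

  expect_equal(qc_verdict(list(pass_rule("a")), good_svm, good_svm)$overall,
               "accept")
  expect_equal(qc_verdict(list(pass_rule("a"), flag_rule("b")))$overall,
               "flag_for_review")
  expect_equal(qc_verdict(list(pass_rule("a")), bad_svm, good_svm)$overall,
               "flag_for_review")

  # monotonicity: adding a flag never turns a flagged verdict into accept
  set.seed(13)
  for (i in 1:20) {
    rules <- lapply(seq_len(sample(1:5, 1)), function(j)
      if (stats::runif(1) < 0.5) pass_rule(paste0("r", j))
      else flag_rule(paste0("r", j)))
    v0 <- qc_verdict(rules)
    v1 <- qc_verdict(c(rules, list(flag_rule("extra"))))
    if (v0$overall == "flag_for_review")
      expect_equal(v1$overall, "flag_for_review")
    expect_equal(v1$overall, "flag_for_review")
  }

  js <- jsonlite::fromJSON(qc_verdict_json(
    qc_verdict(list(flag_rule("closure")), good_svm, NULL)))
  expect_equal(js$overall, "flag_for_review")
  expect_equal(js$rules$rule_id, "closure")
  expect_equal(js$rules$measured, 2)
})

test_that("the QC1 hook is a pass-through that can inject external rules", {
  st <- make_tiny_study()
  expect_length(qc1_hook(st), 0L)
  hk <- function(study) list(cinemetrics:::qc_rule_result(
    "motion_artifact", "flag", 0.9, 0.5, "external detector"))
  res <- qc1_hook(st, hk)
  expect_equal(res[[1]]$rule_id, "motion_artifact")
})
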