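# Post-analysis quality control: geometric consistency rules between SAX and
# LAX segmentations, clinical plausibility rules on the output parameters,
# and SVM curve-shape classifiers, aggregated into an accept / flag-for-review
# verdict. A pluggable pre-analysis hook (`qc1_hook`) lets external image
# quality detectors participate in the verdict.

qc_rule_result <- function(rule_id, status, measured_value, threshold,
                           message = "") {
  if (status == "flag" && !nzchar(message))
    stop("flagged rules must carry a message")
  structure(list(rule_id = rule_id, status = status,
                 measured_value = measured_value, threshold = threshold,
                 message = message), class = "qc_rule_result")
}

#' @export
print.qc_rule_result <- function(x, ...) {
  cat(sprintf("[%s] %s: measured %.3g (threshold %.3g) %s\n", x$status,
              x$rule_id, x$measured_value, x$threshold, x$message))
  invisible(x)
}

# projection of the slice-plane origins / label voxels onto the long axis
lv_extent_sax <- function(sax) {
  nrm <- plane_of(sax, 0L)$normal
  dz <- sax$slice_thickness + sax$slice_gap
  has_lv <- vapply(seq_len(n_slices(sax)), function(s)
    any(sax$labels[, , s, 1] %in% c(LABEL_LV_POOL, LABEL_LV_MYO)), logical(1))
  if (!any(has_lv)) return(NULL)
  cs <- vapply(which(has_lv), function(s)
    sum(nrm * world_coords(sax, c(0, 0, s - 1L))), numeric(1))
  c(min(cs) - dz / 2, max(cs) + dz / 2)
}

lv_extent_lax <- function(lax, nrm) {
  lab <- lax$labels[, , 1, 1]
  idx <- which(lab == LABEL_LV_POOL | lab == LABEL_LV_MYO, arr.ind = TRUE)
  if (nrow(idx) == 0) return(NULL)
  pts <- world_coords(lax, cbind(idx[, 1] - 1L, idx[, 2] - 1L, 0L))
  proj <- pts %*% nrm
  range(proj)
}

overlap_fraction <- function(covering, covered) {
  ov <- min(covering[2], covered[2]) - max(covering[1], covered[1])
  max(ov, 0) / (covered[2] - covered[1])
}

#' Geometric plane-consistency QC rules
#'
#' Three rules evaluated on an aligned study at ED:
#' \describe{
#' \item{intersection}{each LAX plane's intersection line must cross LV
#'   labels in both the most basal and most apical LV-bearing SAX slices;
#'   measured value = fraction of the four crossings present.}
#' \item{missing_slice}{the SAX LV segmentation extent along the long axis
#'   must cover at least `coverage_threshold` of the LAX LV extent
#'   (worst view).}
#' \item{coverage}{symmetric check, LAX extent against SAX extent.}
#' }
#'
#' @param study an aligned `cine_study`.
#' @param coverage_threshold minimum extent fraction (default 0.9).
#' @return list of three `qc_rule_result`s.
#' @export
check_plane_consistency <- function(study, coverage_threshold = 0.9) {
  sax <- study$sax
  has_lv <- vapply(seq_len(n_slices(sax)), function(s)
    any(sax$labels[, , s, 1] %in% c(LABEL_LV_POOL, LABEL_LV_MYO)), logical(1))
  res <- list()
  if (!any(has_lv)) {
    na <- function(id) qc_rule_result(id, "not_applicable", NA_real_, NA_real_,
                                      "no LV segmentation in SAX")
    return(list(na("intersection"), na("missing_slice"), na("coverage")))
  }
  extremes <- range(which(has_lv)) - 1L
  crossings <- logical(0)
  for (k in c("lax2ch", "lax4ch")) {
    pl_l <- plane_of(study[[k]], 0L)
    for (s0 in extremes) {
      li <- intersect_planes(plane_of(sax, s0), pl_l, n_samples = 2L)
      hit <- FALSE
      if (!is.null(li)) {
        len <- sqrt(sum((li$sample_points[2, ] - li$sample_points[1, ])^2))
        tt <- seq(0, len, length.out = max(16L, ceiling(len / min(sax$voxel_size))))
        pts <- t(li$sample_points[1, ] + outer(li$line_direction, tt))
        labs <- sample_slice_labels(sax, s0, pts)
        hit <- any(labs %in% c(LABEL_LV_POOL, LABEL_LV_MYO))
      }
      crossings <- c(crossings, hit)
    }
  }
  frac <- mean(crossings)
  res$intersection <- qc_rule_result(
    "intersection", if (frac < 1) "flag" else "pass", frac, 1,
    if (frac < 1) "LAX plane misses LV in an extreme SAX slice" else "")

  nrm <- plane_of(sax, 0L)$normal
  ext_sax <- lv_extent_sax(sax)
  cov_ms <- Inf; cov_cv <- Inf
  for (k in c("lax2ch", "lax4ch")) {
    ext_lax <- lv_extent_lax(study[[k]], nrm)
    if (is.null(ext_lax)) next
    cov_ms <- min(cov_ms, overlap_fraction(ext_sax, ext_lax))
    cov_cv <- min(cov_cv, overlap_fraction(ext_lax, ext_sax))
  }
  mk_cov <- function(id, cov, msg) {
    if (!is.finite(cov))
      qc_rule_result(id, "not_applicable", NA_real_, coverage_threshold,
                     "no LV segmentation in LAX")
    else qc_rule_result(id, if (cov < coverage_threshold) "flag" else "pass",
                        cov, coverage_threshold,
                        if (cov < coverage_threshold) msg else "")
  }
  res$missing_slice <- mk_cov("missing_slice", cov_ms,
                              "SAX stack does not cover the LAX LV extent")
  res$coverage <- mk_cov("coverage", cov_cv,
                         "LAX segmentation does not reach the SAX extent")
  res
}

#' Clinical plausibility QC rules on the output parameters
#'
#' SV rule: flag when `|LVSV - RVSV| / mean(LVSV, RVSV)` exceeds `sv_tol`
#' (10%). Closure rule: flag when first-to-last-frame volume differs by more
#' than `closure_tol` (10%) of the first-frame volume in either chamber.
#'
#' @param lv,rv `volumetry_report`s for the two chambers.
#' @param lv_curve,rv_curve the corresponding `volume_curve`s.
#' @param sv_tol,closure_tol fractional thresholds (default 0.10).
#' @return list of two `qc_rule_result`s (`sv_difference`, `closure`).
#' @export
check_output_rules <- function(lv, rv, lv_curve, rv_curve,
                               sv_tol = 0.10, closure_tol = 0.10) {
  res <- list()
  msv <- mean(c(lv$sv, rv$sv))
  if (msv <= 0) {
    res$sv_difference <- qc_rule_result("sv_difference", "flag", NA_real_,
                                        sv_tol, "degenerate SV")
  } else {
    d <- abs(lv$sv - rv$sv) / msv
    res$sv_difference <- qc_rule_result(
      "sv_difference", if (d > sv_tol) "flag" else "pass", d, sv_tol,
      if (d > sv_tol)
        sprintf("LV/RV stroke volumes differ by %.1f%%", 100 * d) else "")
  }
  gap <- max(vapply(list(lv_curve, rv_curve), function(cv) {
    v <- cv$values
    abs(v[1] - v[length(v)]) / v[1]
  }, numeric(1)))
  res$closure <- qc_rule_result(
    "closure", if (gap > closure_tol) "flag" else "pass", gap, closure_tol,
    if (gap > closure_tol)
      sprintf("first/last-phase volumes differ by %.1f%%", 100 * gap) else "")
  res
}

#' Shape features of a volume or strain curve
#'
#' Concatenates (a) the curve resampled to 32 points and normalized to unit
#' amplitude, and (b) scalar shape descriptors: relative excursion, closure
#' gap, maximum frame-to-frame jump, and time of the extremum as a cycle
#' fraction. Deterministic given the curve; constant curves are guarded.
#'
#' @param curve numeric vector (length >= 20).
#' @return named numeric feature vector.
#' @export
curve_features <- function(curve) {
  n <- length(curve)
  if (n < 20) stop("curve must have at least 20 samples")
  tfrac <- (seq_len(n) - 1) / n
  shape <- stats::approx(tfrac, curve, xout = (0:31) / 32, rule = 2)$y
  amp <- max(curve) - min(curve)
  if (amp < 1e-9) amp <- 1
  shape_n <- (shape - min(shape)) / amp
  c(stats::setNames(shape_n, paste0("s", 1:32)),
    excursion = (max(curve) - min(curve)) / max(abs(max(curve)), 1e-9),
    closure_gap = abs(curve[1] - curve[n]) / amp,
    max_jump = max(abs(diff(curve))) / amp,
    t_extremum = (which.max(abs(curve - curve[1])) - 1) / n)
}

#' Train a curve-shape QC classifier
#'
#' Soft-margin kernel SVM on standardized [curve_features()], with k-fold
#' cross-validated balanced accuracy. One classifier is trained per curve
#' type (volume or strain).
#'
#' @param dataset output of [make_curve_dataset()].
#' @param type `"volume"` or `"strain"`.
#' @param kernel,C,gamma SVM hyperparameters (RBF kernel, C = 1 by default;
#'   `gamma = NULL` uses the e1071 default, 1/n_features, on standardized
#'   features).
#' @param folds cross-validation folds (5).
#' @param seed integer; fixes fold assignment and SVM internals.
#' @return object of class `qc_svm`: fitted model, `cv_bacc`, `type`.
#' @export
train_qc_svm <- function(dataset, type = c("volume", "strain"),
                         kernel = "radial", C = 1, gamma = NULL,
                         folds = 5L, seed = 1L) {
  type <- match.arg(type)
  sel <- dataset$type == type
  y <- factor(dataset$label[sel], levels = c("good", "bad"))
  if (length(unique(y)) < 2L) stop("dataset must contain both classes")
  X <- t(vapply(dataset$curves[sel], curve_features, numeric(36)))
  set.seed(seed)
  fold <- sample(rep_len(seq_len(folds), nrow(X)))
  baccs <- vapply(seq_len(folds), function(k) {
    tr <- fold != k
    fit <- fit_svm(X[tr, , drop = FALSE], y[tr], kernel, C, gamma, seed)
    pred <- stats::predict(fit, X[!tr, , drop = FALSE])
    balanced_accuracy(pred == "bad", y[!tr] == "bad")
  }, numeric(1))
  model <- fit_svm(X, y, kernel, C, gamma, seed)
  structure(list(model = model, cv_bacc = mean(baccs), type = type,
                 version = as.character(utils::packageVersion("cinemetrics"))),
            class = "qc_svm")
}

fit_svm <- function(X, y, kernel, C, gamma, seed) {
  set.seed(seed)
  args <- list(x = X, y = y, kernel = kernel, cost = C, scale = TRUE)
  if (!is.null(gamma)) args$gamma <- gamma
  do.call(e1071::svm, args)
}

balanced_accuracy <- function(pred_pos, true_pos) {
  sens <- if (any(true_pos)) mean(pred_pos[true_pos]) else NA_real_
  spec <- if (any(!true_pos)) mean(!pred_pos[!true_pos]) else NA_real_
  mean(c(sens, spec), na.rm = TRUE)
}

#' Classify a curve with a trained QC SVM
#'
#' @param classifier a `qc_svm`.
#' @param curve numeric vector.
#' @return list with `label` (`"good"` or `"anomalous"`) and `margin`
#'   (signed decision value, positive toward anomalous).
#' @export
predict_qc_svm <- function(classifier, curve) {
  X <- matrix(curve_features(curve), 1L)
  colnames(X) <- colnames(classifier$model$SV)
  pred <- stats::predict(classifier$model, X, decision.values = TRUE)
  dv <- drop(attr(pred, "decision.values"))
  # orient margin toward "bad" regardless of which class e1071 put first
  sign_flip <- if (grepl("^good", colnames(attr(pred, "decision.values"))[1])) 1 else -1
  list(label = if (pred[1] == "bad") "anomalous" else "good",
       margin = unname(sign_flip * -dv))
}

#' Save / load a trained QC classifier
#' @param classifier a `qc_svm`.
#' @param path file path.
#' @export
save_qc_svm <- function(classifier, path) {
  saveRDS(classifier, path, version = 2)
  invisible(path)
}

#' @rdname save_qc_svm
#' @export
load_qc_svm <- function(path) readRDS(path)

#' Aggregate QC results into a verdict
#'
#' The exam is flagged for review iff any rule flags or any SVM labels its
#' curve anomalous; `not_applicable` rules never flag.
#'
#' @param rules list of `qc_rule_result`s.
#' @param svm_vol_result,svm_strain_result optional outputs of
#'   [predict_qc_svm()].
#' @return object of class `qc_verdict` with `rules`, `svm`, `overall`.
#' @export
qc_verdict <- function(rules, svm_vol_result = NULL, svm_strain_result = NULL) {
  any_rule_flag <- any(vapply(rules, function(r) r$status == "flag", logical(1)))
  any_svm <- any(vapply(list(svm_vol_result, svm_strain_result), function(s)
    !is.null(s) && s$label == "anomalous", logical(1)))
  structure(list(
    rules = rules,
    svm = list(volume = svm_vol_result, strain = svm_strain_result),
    overall = if (any_rule_flag || any_svm) "flag_for_review" else "accept"),
    class = "qc_verdict")
}

#' @export
print.qc_verdict <- function(x, ...) {
  cat(sprintf("<qc_verdict: %s (%d rule(s) flagged)>\n", x$overall,
              sum(vapply(x$rules, function(r) r$status == "flag", logical(1)))))
  invisible(x)
}

#' Serialize a QC verdict to JSON
#' @param verdict a `qc_verdict`.
#' @return JSON string with every rule's measured value for audit.
#' @export
qc_verdict_json <- function(verdict) {
  payload <- list(
    rules = lapply(unname(verdict$rules), function(r)
      list(rule_id = r$rule_id, status = r$status, measured = r$measured_value,
           threshold = r$threshold, message = r$message)),
    svm = lapply(verdict$svm, function(s)
      if (is.null(s)) NULL else list(label = s$label, margin = s$margin)),
    overall = verdict$overall)
  jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, null = "null")
}

#' Pre-analysis QC hook
#'
#' Pluggable attachment point for external image-quality detectors (motion
#' artefact or view-planning classifiers). The default hook accepts every
#' study; a user-supplied hook receives the study and returns a list of
#' `qc_rule_result`s merged into the verdict.
#'
#' @param study a `cine_study`.
#' @param hook function(study) -> list of `qc_rule_result`, or `NULL`.
#' @return list of `qc_rule_result`s (possibly empty).
#' @export
qc1_hook <- function(study, hook = NULL) {
  if (is.null(hook)) return(list())
  hook(study)
}
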