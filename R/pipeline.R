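# Orchestration: full per-case pipeline (read -> align -> volumetrics ->
# strain -> QC), cohort processing with reference-value extraction, phantom
# bundle export, and single-panel case reports. Any stage failure is
# converted into a QC flag naming the stage - a case report always carries a
# verdict.

#' Pipeline configuration
#'
#' @param align run SAX/LAX breath-hold alignment before volumetry.
#' @param max_shift_mm,tol_mm,max_iter alignment settings.
#' @param harmonics Fourier harmonics for curve smoothing.
#' @param sv_tol,closure_tol,coverage_threshold QC rule thresholds.
#' @param strain_method `"fields"` (displacement-field input) or
#'   `"demons"` (built-in intensity tracker).
#' @param svm_vol,svm_strain optional trained [train_qc_svm()] classifiers
#'   (or file paths to saved ones).
#' @param qc1 optional pre-analysis hook, `function(study)` returning
#'   `qc_rule_result`s.
#' @param output_dir directory for cohort outputs.
#' @param seed seed for all stochastic steps.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(align = TRUE, max_shift_mm = 15, tol_mm = 0.1,
                            max_iter = 10L, harmonics = 10L,
                            sv_tol = 0.10, closure_tol = 0.10,
                            coverage_threshold = 0.9,
                            strain_method = c("fields", "demons"),
                            svm_vol = NULL, svm_strain = NULL, qc1 = NULL,
                            output_dir = ".", seed = 17L) {
  strain_method <- match.arg(strain_method)
  stopifnot(max_shift_mm > 0, tol_mm > 0, harmonics > 0,
            sv_tol > 0, closure_tol > 0, coverage_threshold > 0)
  load_svm <- function(x) if (is.character(x)) load_qc_svm(x) else x
  structure(list(align = align, max_shift_mm = max_shift_mm, tol_mm = tol_mm,
                 max_iter = max_iter, harmonics = harmonics, sv_tol = sv_tol,
                 closure_tol = closure_tol,
                 coverage_threshold = coverage_threshold,
                 strain_method = strain_method,
                 svm_vol = load_svm(svm_vol), svm_strain = load_svm(svm_strain),
                 qc1 = qc1, output_dir = output_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(config[setdiff(names(config), c("svm_vol", "svm_strain", "qc1"))],
          f, version = 2)
  unname(tools::md5sum(f))
}

#' Export a phantom as an on-disk bundle with ground truth
#'
#' Writes the study in the standard NIfTI+JSON bundle layout plus the
#' phantom's ground truth: the analytic volume curves and closed-form cycle
#' parameters (`truth_curves.csv`, `truth_params.json`) and, when present,
#' the displacement fields as 5-D NIfTI (`<view>_field.nii.gz`, mm).
#'
#' @param phantom a `phantom`.
#' @param bundle_path output directory.
#' @return `bundle_path`, invisibly.
#' @export
write_phantom_bundle <- function(phantom, bundle_path) {
  write_study(phantom$study, bundle_path)
  tr <- phantom$truth
  utils::write.csv(data.frame(frame = seq_along(tr$tfrac) - 1L,
                              time_s = tr$frame_times,
                              lv_ml = tr$lv_volume, rv_ml = tr$rv_volume),
                   file.path(bundle_path, "truth_curves.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(lv = tr$lv_params, rv = tr$rv_params,
                            lv_wall_volume_ml = tr$lv_wall_volume),
                       file.path(bundle_path, "truth_params.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(tr$fields)) {
    for (k in names(tr$fields)) {
      img <- RNifti::asNifti(tr$fields[[k]])
      RNifti::writeNifti(img, file.path(bundle_path,
                                        paste0(k, "_field.nii.gz")))
    }
  }
  invisible(bundle_path)
}

read_bundle_fields <- function(bundle_path) {
  out <- list()
  for (k in c("sax", "lax2ch", "lax4ch")) {
    f <- file.path(bundle_path, paste0(k, "_field.nii.gz"))
    if (file.exists(f)) out[[k]] <- as.array(RNifti::readNifti(f))
  }
  if (length(out)) out else NULL
}

#' Run the full analysis pipeline on one exam
#'
#' Stages in order: read, align, volumetrics (LV and RV curves, mass, cycle
#' parameters), feature-tracking strain, post-analysis QC. A stage exception
#' never aborts the case: it is converted into a QC flag naming the stage,
#' and the report always carries a verdict.
#'
#' @param x a bundle directory path, `cine_study`, or `phantom` (whose
#'   ground-truth fields are used for strain when present).
#' @param config a [pipeline_config()].
#' @param fields optional displacement fields (overrides bundle/phantom
#'   fields).
#' @param id case identifier recorded in the report.
#' @return object of class `case_report`: `lv`, `rv` (`volumetry_report`),
#'   `lv_curve`, `rv_curve`, `strain`, `alignment`, `qc`, `provenance`.
#' @export
run_pipeline <- function(x, config = pipeline_config(), fields = NULL,
                         id = "case") {
  stage_flags <- list()
  note_failure <- function(stage, e) {
    stage_flags[[stage]] <<- qc_rule_result(
      paste0("stage_", stage), "flag", NA_real_, NA_real_,
      paste0(stage, " failed: ", conditionMessage(e)))
  }

  study <- NULL
  if (is.character(x)) {
    study <- read_study(x)
    if (is.null(fields)) fields <- read_bundle_fields(x)
  } else if (inherits(x, "phantom")) {
    study <- x$study
    if (is.null(fields)) fields <- x$truth$fields
  } else if (inherits(x, "cine_study")) {
    study <- x
  } else stop("x must be a bundle path, cine_study or phantom")

  alignment <- NULL
  if (config$align) {
    tryCatch({
      al <- align_study(study, config$max_shift_mm, config$tol_mm,
                        config$max_iter)
      alignment <- al$result
      study <- al$study
    }, error = function(e) note_failure("align", e))
  }

  lv <- rv <- lv_curve <- rv_curve <- NULL
  tryCatch({
    lv_curve <- volume_curve(study$sax, LABEL_LV_POOL, "LV", config$harmonics)
    rv_curve <- volume_curve(study$sax, LABEL_RV_POOL, "RV", config$harmonics)
    subj <- study$subject
    bsa <- if (!is.na(subj$height) && !is.na(subj$weight))
      bsa_dubois(subj$height, subj$weight) else NULL
    lvm <- tryCatch(lv_mass(study$sax), error = function(e) NULL)
    lv <- cycle_parameters(lv_curve, bsa = bsa, lvm = lvm)
    rv <- cycle_parameters(rv_curve, bsa = bsa)
  }, error = function(e) note_failure("volumetrics", e))

  strain <- NULL
  tryCatch({
    if (config$strain_method == "fields" && is.null(fields)) {
      if (!is.null(study$images)) config$strain_method <- "demons"
      else stop("no displacement fields available")
    }
    contours <- sample_ed_contours(study)
    tracked <- track_contours(contours, study, fields = fields,
                              method = config$strain_method)
    strain <- strain_curves(tracked, study$sax$frame_times)
  }, error = function(e) note_failure("strain", e))

  rules <- list()
  tryCatch({
    rules <- c(qc1_hook(study, config$qc1),
               check_plane_consistency(study, config$coverage_threshold))
    if (!is.null(lv) && !is.null(rv))
      rules <- c(rules, check_output_rules(lv, rv, lv_curve, rv_curve,
                                           config$sv_tol, config$closure_tol))
  }, error = function(e) note_failure("qc", e))
  rules <- c(rules, stage_flags)

  svm_vol_res <- if (!is.null(config$svm_vol) && !is.null(lv_curve))
    predict_qc_svm(config$svm_vol, lv_curve$values) else NULL
  svm_strain_res <- if (!is.null(config$svm_strain) && !is.null(strain))
    predict_qc_svm(config$svm_strain, strain$ecc) else NULL
  verdict <- qc_verdict(rules, svm_vol_res, svm_strain_res)

  structure(list(
    id = id, lv = lv, rv = rv, lv_curve = lv_curve, rv_curve = rv_curve,
    strain = strain, alignment = alignment, qc = verdict,
    provenance = list(
      package_version = as.character(utils::packageVersion("cinemetrics")),
      config_hash = config_hash(config), seed = config$seed)),
    class = "case_report")
}

#' @export
print.case_report <- function(x, ...) {
  cat(sprintf("<case_report %s: %s>\n", x$id, x$qc$overall))
  if (!is.null(x$lv)) print(x$lv)
  invisible(x)
}

#' Flatten a case report to a one-row data frame
#' @param report a `case_report`.
#' @return one-row data frame with volumetry, strain and QC columns.
#' @export
as.data.frame.case_report <- function(x, ...) {
  out <- data.frame(id = x$id, qc_overall = x$qc$overall)
  if (!is.null(x$lv)) out <- cbind(out, as.data.frame(x$lv))
  if (!is.null(x$rv)) out <- cbind(out, as.data.frame(x$rv))
  if (!is.null(x$strain)) out <- cbind(out, as.data.frame(x$strain))
  out
}

#' Process a cohort of exams
#'
#' Runs [run_pipeline()] on every case, writes (optionally) the per-case
#' table, and feeds QC-accepted cases into [reference_values()].
#'
#' @param bundles a directory whose sub-directories are bundles, or a list
#'   of inputs accepted by [run_pipeline()].
#' @param config a [pipeline_config()].
#' @param subjects optional data frame with `sex` and `age` per case (taken
#'   from the bundle sidecars otherwise).
#' @param parameters parameter columns for the reference table (defaults to
#'   the main volumetric and strain indices present).
#' @param write_outputs write `cohort.csv` and `reference_table.csv` under
#'   `config$output_dir`.
#' @return list with `cases` (reports), `table` (per-case data frame),
#'   `reference` (a `reference_table` or `NULL` with a warning when every
#'   case is flagged), `summary` (accepted/flagged counts by reason).
#' @export
run_cohort <- function(bundles, config = pipeline_config(), subjects = NULL,
                       parameters = NULL, write_outputs = FALSE) {
  if (is.character(bundles)) {
    if (!dir.exists(bundles)) stop("no such directory: ", bundles)
    paths <- list.dirs(bundles, recursive = FALSE)
    if (length(paths) == 0) stop("no bundles found in ", bundles)
    inputs <- as.list(paths)
    ids <- basename(paths)
  } else {
    if (length(bundles) == 0) stop("no bundles supplied")
    inputs <- bundles
    ids <- names(bundles) %||% sprintf("case%03d", seq_along(bundles))
  }
  cases <- Map(function(x, id) run_pipeline(x, config, id = id), inputs, ids)
  tab <- do.call(rbind, lapply(cases, as.data.frame))
  # subject covariates for stratification
  get_subject <- function(x) {
    st <- if (inherits(x, "phantom")) x$study
    else if (inherits(x, "cine_study")) x
    else read_study(x)
    data.frame(sex = st$subject$sex, age = st$subject$age)
  }
  subj_df <- subjects %||% do.call(rbind, lapply(inputs, get_subject))
  tab <- cbind(tab, subj_df)

  accepted <- tab$qc_overall == "accept"
  flag_reasons <- table(unlist(lapply(cases, function(cr)
    vapply(Filter(function(r) r$status == "flag", cr$qc$rules),
           `[[`, character(1), "rule_id"))))
  reference <- NULL
  if (!any(accepted)) {
    warning("all cases flagged; reference table unavailable")
  } else {
    if (is.null(parameters))
      parameters <- intersect(c("lv_edv_ml", "lv_esv_ml", "lv_sv_ml",
                                "lv_ef_pct", "rv_edv_ml", "rv_esv_ml",
                                "rv_sv_ml", "rv_ef_pct", "ecc_pct"),
                              names(tab))
    reference <- suppressWarnings(
      reference_values(tab[accepted, , drop = FALSE], parameters))
  }
  if (write_outputs) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(tab, file.path(config$output_dir, "cohort.csv"),
                     row.names = FALSE)
    if (!is.null(reference))
      utils::write.csv(reference,
                       file.path(config$output_dir, "reference_table.csv"),
                       row.names = FALSE)
  }
  list(cases = cases, table = tab, reference = reference,
       summary = list(n = length(cases), accepted = sum(accepted),
                      flagged = sum(!accepted),
                      flag_reasons = flag_reasons))
}

#' Render a single-panel case report
#'
#' One raster page per case: mid-cycle segmentation overlays (three SAX
#' slices and both LAX views), LV/RV volume curves, strain curves, the main
#' parameters, and a QC banner when the case is flagged. Missing components
#' render as placeholders.
#'
#' @param report a `case_report`.
#' @param study the `cine_study` the report came from (for overlays); may be
#'   `NULL`.
#' @param file output PNG path.
#' @param width,height,res device settings.
#' @return invisibly, a list with `file` and `banner` (the QC banner text,
#'   empty when accepted).
#' @export
render_panel <- function(report, study = NULL, file = "panel.png",
                         width = 1400, height = 900, res = 110) {
  banner <- if (report$qc$overall == "flag_for_review") {
    ids <- vapply(Filter(function(r) r$status == "flag", report$qc$rules),
                  `[[`, character(1), "rule_id")
    paste("FLAG FOR REVIEW:", paste(ids, collapse = ", "))
  } else ""
  grDevices::png(file, width = width, height = height, res = res)
  on.exit(grDevices::dev.off())
  graphics::layout(matrix(c(1, 2, 3, 4, 5, 6, 6, 7, 7, 8), 2, 5, byrow = TRUE))
  old <- graphics::par(mar = c(2.5, 2.5, 2, 0.5), mgp = c(1.5, 0.4, 0))
  on.exit(graphics::par(old), add = TRUE)

  placeholder <- function(txt) {
    graphics::plot.new(); graphics::box()
    graphics::text(0.5, 0.5, txt, cex = 0.9, col = "grey40")
  }
  overlay <- function(stack, slice0, title) {
    f <- max(1L, round(n_frames(stack) / 3))
    lab <- stack$labels[, , slice0 + 1L, f]
    cols <- c("black", "firebrick", "orange", "steelblue")
    graphics::image(lab, col = cols[sort(unique(as.vector(lab))) + 1L],
                    axes = FALSE, main = title, cex.main = 0.9)
  }
  if (!is.null(study)) {
    ns <- n_slices(study$sax)
    picks <- unique(pmax(1L, round(ns * c(0.25, 0.5, 0.75))))
    for (i in seq_len(3)) {
      s <- picks[min(i, length(picks))]
      overlay(study$sax, s - 1L, sprintf("SAX slice %d", s - 1L))
    }
    overlay(study$lax2ch, 0L, "2CH")
    overlay(study$lax4ch, 0L, "4CH")
  } else {
    for (i in 1:5) placeholder("no images")
  }

  if (!is.null(report$lv_curve)) {
    tt <- report$lv_curve$times
    graphics::plot(tt, report$lv_curve$values, type = "l", lwd = 2,
                   col = "firebrick", xlab = "time (s)", ylab = "volume (ml)",
                   main = "Volume curves",
                   ylim = range(c(report$lv_curve$values,
                                  report$rv_curve$values)))
    graphics::lines(tt, report$rv_curve$values, lwd = 2, col = "steelblue")
    graphics::legend("bottomleft", c("LV", "RV"), lwd = 2, bty = "n",
                     col = c("firebrick", "steelblue"), cex = 0.8)
  } else placeholder("volumetrics unavailable")

  if (!is.null(report$strain)) {
    tt <- report$strain$frame_times
    graphics::plot(tt, report$strain$ecc, type = "l", lwd = 2,
                   col = "firebrick", xlab = "time (s)", ylab = "strain (%)",
                   main = "Strain curves",
                   ylim = range(c(report$strain$ecc, report$strain$err,
                                  report$strain$ell_2ch, report$strain$ell_4ch)))
    graphics::lines(tt, report$strain$err, lwd = 2, col = "orange")
    graphics::lines(tt, report$strain$ell_2ch, lwd = 2, col = "steelblue")
    graphics::lines(tt, report$strain$ell_4ch, lwd = 2, col = "seagreen")
    graphics::legend("topright", c("circ", "rad", "long 2CH", "long 4CH"),
                     lwd = 2, bty = "n", cex = 0.7,
                     col = c("firebrick", "orange", "steelblue", "seagreen"))
  } else placeholder("strain unavailable")

  graphics::plot.new(); graphics::box()
  lines_txt <- c(sprintf("case %s", report$id))
  if (!is.null(report$lv))
    lines_txt <- c(lines_txt,
                   sprintf("LV EDV %.0f  ESV %.0f  SV %.0f ml  EF %.0f%%",
                           report$lv$edv, report$lv$esv, report$lv$sv,
                           report$lv$ef),
                   sprintf("RV EDV %.0f  ESV %.0f ml  EF %.0f%%",
                           report$rv$edv, report$rv$esv, report$rv$ef))
  if (!is.null(report$strain))
    lines_txt <- c(lines_txt,
                   sprintf("peak ecc %.1f%%  ell %.1f/%.1f%%",
                           report$strain$peaks$ecc,
                           report$strain$peaks$ell_2ch,
                           report$strain$peaks$ell_4ch))
  lines_txt <- c(lines_txt, if (nzchar(banner)) banner else "QC: accept")
  graphics::text(0.02, seq(0.9, by = -0.12, length.out = length(lines_txt)),
                 lines_txt, adj = 0, cex = 0.85,
                 col = ifelse(grepl("^FLAG", lines_txt), "red", "black"))
  invisible(list(file = file, banner = banner))
}
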