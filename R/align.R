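# Iterative SAX <-> LAX breath-hold alignment.
#
# Each SAX slice (and then each LAX view) receives an in-plane translation
# that minimizes the mismatch between LV label transitions seen along the
# SAX/LAX plane-intersection lines in the two views. Only the ED frame drives
# the optimization (a breath-hold offset is constant within one cine
# acquisition); the correction is applied to all frames of that slice.

# sample labels of one slice along world points, with an in-plane shift
# (mm along the slice row/col axes) applied to the slice content
sample_slice_labels <- function(stack, slice0, pts, shift_mm = c(0, 0)) {
  v <- voxel_coords(stack, pts)
  e_r_len <- sqrt(sum(stack$affine[1:3, 1]^2))
  e_c_len <- sqrt(sum(stack$affine[1:3, 2]^2))
  r <- round(v[, 1] - shift_mm[1] / e_r_len) + 1L
  c <- round(v[, 2] - shift_mm[2] / e_c_len) + 1L
  d <- dim(stack$labels)
  ok <- r >= 1 & r <= d[1] & c >= 1 & c <= d[2]
  out <- integer(nrow(v))
  out[ok] <- stack$labels[cbind(r[ok], c[ok], slice0 + 1L, 1L)]
  out
}

# sub-voxel LV indicator along world points: bilinear interpolation of the
# binary LV mask of one slice, with an in-plane shift applied to the content
sample_slice_indicator <- function(stack, slice0, pts, shift_mm = c(0, 0)) {
  v <- voxel_coords(stack, pts)
  e_r_len <- sqrt(sum(stack$affine[1:3, 1]^2))
  e_c_len <- sqrt(sum(stack$affine[1:3, 2]^2))
  r <- v[, 1] - shift_mm[1] / e_r_len + 1
  c <- v[, 2] - shift_mm[2] / e_c_len + 1
  lab <- stack$labels[, , slice0 + 1L, 1L]
  mask <- (lab == LABEL_LV_POOL | lab == LABEL_LV_MYO) + 0
  bilinear(mask, r, c)
}

# positions (mm along the line) where the indicator crosses 0.5, localized
# by linear interpolation between samples
transition_points <- function(indicator, tt) {
  a <- indicator - 0.5
  flips <- which(a[-1] * a[-length(a)] < 0)
  if (length(flips) == 0L) return(numeric(0))
  frac <- -a[flips] / (a[flips + 1L] - a[flips])
  tt[flips] + frac * (tt[flips + 1L] - tt[flips])
}

line_spacing <- function(study) min(study$sax$voxel_size) / 2

# mismatch of one SAX slice against one LAX view along their intersection
# line; returns NA when the planes miss each other's field of view
slice_view_mismatch <- function(study, slice0, lax_key, sax_shift = c(0, 0),
                                lax_shift = c(0, 0)) {
  sax <- study$sax; lax <- study[[lax_key]]
  pl_s <- plane_of(sax, slice0)
  pl_l <- plane_of(lax, 0L)
  li <- intersect_planes(pl_s, pl_l, n_samples = 2L)
  if (is.null(li)) return(NA_real_)
  len <- sqrt(sum((li$sample_points[2, ] - li$sample_points[1, ])^2))
  ns <- max(16L, ceiling(len / line_spacing(study)))
  tt <- seq(0, len, length.out = ns)
  pts <- t(li$sample_points[1, ] + outer(li$line_direction, tt))
  ts <- transition_points(sample_slice_indicator(sax, slice0, pts, sax_shift), tt)
  tl <- transition_points(sample_slice_indicator(lax, 0L, pts, lax_shift), tt)
  if (length(ts) == 0L || length(tl) == 0L) return(NA_real_)
  k <- min(length(ts), length(tl))
  # pair boundary crossings in order from both ends of the chord
  ts <- sort(ts); tl <- sort(tl)
  pick <- function(x, k) c(utils::head(x, ceiling(k / 2)), utils::tail(x, floor(k / 2)))
  mean(abs(pick(ts, k) - pick(tl, k)))
}

#' Mismatch score of one SAX slice against the LAX views
#'
#' Mean absolute distance (mm), along the SAX/LAX plane-intersection lines,
#' between the LV label-transition points seen in the SAX slice and in the
#' LAX views, with an optional candidate in-plane shift applied to the SAX
#' slice content.
#'
#' @param study a `cine_study`.
#' @param slice_index 0-based SAX slice index.
#' @param shift candidate in-plane shift (mm along row/col axes).
#' @param lax_shifts named list of current LAX in-plane shifts.
#' @return score in mm, or `NA` if neither LAX view yields an intersection
#'   with visible LV.
#' @export
mismatch_score <- function(study, slice_index, shift = c(0, 0),
                           lax_shifts = list(lax2ch = c(0, 0),
                                             lax4ch = c(0, 0))) {
  s <- vapply(c("lax2ch", "lax4ch"), function(k)
    slice_view_mismatch(study, slice_index, k, shift, lax_shifts[[k]]),
    numeric(1))
  if (all(is.na(s))) NA_real_ else mean(s, na.rm = TRUE)
}

# coordinate-descent search of an in-plane shift: coarse grid over the full
# search radius, fine 0.5 mm grid around the coarse optimum. The objective
# carries a small shift-magnitude penalty (minimal-motion prior) so that
# quantization plateaus in the transition-point score do not pull
# already-consistent slices away from zero.
SHIFT_PENALTY_PER_MM <- 0.1

search_shift <- function(score_fun, start, max_shift, sweeps = 2L) {
  pen <- function(s) {
    sc <- score_fun(s)
    if (is.na(sc)) NA_real_ else sc + SHIFT_PENALTY_PER_MM * sqrt(sum(s^2))
  }
  sh <- start
  for (sw in seq_len(sweeps)) {
    for (axis in 1:2) {
      coarse <- seq(-max_shift, max_shift, by = 2)
      sc <- vapply(coarse, function(a) { s <- sh; s[axis] <- a; pen(s) },
                   numeric(1))
      if (all(is.na(sc))) return(list(shift = start, score = NA_real_))
      best <- coarse[which.min(sc)]
      fine <- seq(best - 2, best + 2, by = 0.5)
      fine <- fine[abs(fine) <= max_shift]
      sc <- vapply(fine, function(a) { s <- sh; s[axis] <- a; pen(s) },
                   numeric(1))
      sh[axis] <- fine[which.min(sc)]
    }
  }
  list(shift = sh, score = score_fun(sh))
}

# golden-section refinement along one axis (penalized objective)
refine_axis <- function(score_fun, sh, axis, radius = 0.5, tol = 0.05) {
  f <- function(a) {
    s <- sh; s[axis] <- a
    sc <- score_fun(s)
    if (is.na(sc)) Inf else sc + SHIFT_PENALTY_PER_MM * sqrt(sum(s^2))
  }
  opt <- stats::optimize(f, c(sh[axis] - radius, sh[axis] + radius), tol = tol)
  if (opt$objective < f(sh[axis])) sh[axis] <- opt$minimum
  sh
}

#' Iteratively align SAX slices and LAX views
#'
#' Alternates between per-SAX-slice in-plane shifts (against both LAX views)
#' and per-LAX-view in-plane shifts (against the shifted SAX stack), each
#' found by coordinate descent on a 0.5 mm grid with golden-section
#' refinement, until the largest shift update drops below `tol_mm` or
#' `max_iter` is reached. Slices without a usable intersection keep zero
#' shift and are recorded as warnings.
#'
#' @param study a `cine_study` (ED-frame segmentations must be non-empty).
#' @param max_shift_mm search radius per slice, mm.
#' @param tol_mm convergence tolerance on shift updates, mm.
#' @param max_iter maximum alternation count.
#' @return list with `result` (class `alignment_result`: `per_slice_shift`
#'   matrix in mm, `lax_shift`, `n_iterations`, `converged`, `residual`,
#'   `warnings`) and `study` (the aligned copy, shifts applied to label
#'   content at nearest-voxel precision).
#' @export
align_study <- function(study, max_shift_mm = 15, tol_mm = 0.1, max_iter = 10L) {
  ns <- n_slices(study$sax)
  shifts <- matrix(0, ns, 2)
  lax_shifts <- list(lax2ch = c(0, 0), lax4ch = c(0, 0))
  warns <- character(0)
  converged <- FALSE
  it <- 0L
  repeat {
    it <- it + 1L
    max_update <- 0
    for (s in seq_len(ns)) {
      # apex cap slices (no blood pool) give an unreliable objective: the
      # wall-boundary chord changes too fast along the long axis
      if (!any(study$sax$labels[, , s, 1] == LABEL_LV_POOL)) {
        if (it == 1L)
          warns <- c(warns, sprintf("slice %d: no LV pool, kept unshifted", s - 1L))
        next
      }
      f <- function(sh) mismatch_score(study, s - 1L, sh, lax_shifts)
      if (is.na(f(shifts[s, ]))) {
        if (it == 1L)
          warns <- c(warns, sprintf("slice %d: no usable LAX intersection", s - 1L))
        next
      }
      res <- search_shift(f, shifts[s, ], max_shift_mm)
      sh <- res$shift
      for (axis in 1:2) sh <- refine_axis(f, sh, axis)
      max_update <- max(max_update, sqrt(sum((sh - shifts[s, ])^2)))
      shifts[s, ] <- sh
    }
    # refine LAX views against the shifted SAX stack
    for (k in c("lax2ch", "lax4ch")) {
      g <- function(lsh) {
        ls2 <- lax_shifts; ls2[[k]] <- lsh
        sc <- vapply(seq_len(ns), function(s)
          slice_view_mismatch(study, s - 1L, k, shifts[s, ], lsh), numeric(1))
        if (all(is.na(sc))) NA_real_ else mean(sc, na.rm = TRUE)
      }
      if (!is.na(g(lax_shifts[[k]]))) {
        res <- search_shift(g, lax_shifts[[k]], max_shift_mm)
        max_update <- max(max_update,
                          sqrt(sum((res$shift - lax_shifts[[k]])^2)))
        lax_shifts[[k]] <- res$shift
      }
    }
    if (max_update < tol_mm) { converged <- TRUE; break }
    if (it >= max_iter) break
  }
  resid <- vapply(seq_len(ns), function(s)
    mismatch_score(study, s - 1L, shifts[s, ], lax_shifts), numeric(1))
  result <- structure(list(
    per_slice_shift = shifts,
    lax_shift = lax_shifts,
    n_iterations = it,
    converged = converged,
    residual = mean(resid, na.rm = TRUE),
    warnings = warns), class = "alignment_result")
  list(result = result, study = apply_alignment(study, result))
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("<alignment_result: %d iteration(s), %s, residual %.2f mm>\n",
              x$n_iterations, if (x$converged) "converged" else "not converged",
              x$residual))
  invisible(x)
}

# apply per-slice and LAX shifts to label content (nearest voxel)
apply_alignment <- function(study, result) {
  for (s in seq_len(nrow(result$per_slice_shift))) {
    sh <- result$per_slice_shift[s, ]
    if (sqrt(sum(sh^2)) >= min(study$sax$voxel_size) / 2)
      study$sax <- shift_slice_labels(study$sax, s - 1L, sqrt(sum(sh^2)),
                                      sh)
  }
  for (k in c("lax2ch", "lax4ch")) {
    sh <- result$lax_shift[[k]]
    if (sqrt(sum(sh^2)) >= min(study[[k]]$voxel_size) / 2)
      study[[k]] <- shift_slice_labels(study[[k]], 0L, sqrt(sum(sh^2)), sh)
  }
  study
}
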