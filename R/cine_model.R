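# Core data types for segmented cine exams: labelled 4-D stacks with world
# geometry, study bundles (SAX + two LAX views), plane algebra, and NIfTI+JSON
# bundle I/O.

LABEL_BACKGROUND <- 0L
LABEL_LV_POOL <- 1L
LABEL_LV_MYO <- 2L
LABEL_RV_POOL <- 3L
VALID_LABELS <- c(LABEL_BACKGROUND, LABEL_LV_POOL, LABEL_LV_MYO, LABEL_RV_POOL)
VALID_VIEWS <- c("SAX", "LAX2CH", "LAX4CH")

#' Construct a labelled cine stack
#'
#' A `labelled_stack` is a 4-D integer label grid indexed
#' `(row, col, slice, frame)` together with the geometry needed to place every
#' voxel in world (scanner) coordinates. Label codes follow the biventricular
#' convention: 0 background, 1 LV blood pool, 2 LV myocardium, 3 RV blood pool.
#'
#' @param labels integer array, dims `(rows, cols, slices, frames)`.
#' @param affine 4x4 matrix mapping homogeneous 0-based voxel indices
#'   `(row, col, slice, 1)` to world coordinates in mm.
#' @param voxel_size length-2 numeric, in-plane spacing `(dr, dc)` in mm.
#' @param slice_thickness,slice_gap slice geometry in mm; the slice-to-slice
#'   world spacing is `slice_thickness + slice_gap`.
#' @param frame_times numeric vector of frame times in seconds, starting at 0,
#'   strictly increasing, one per frame.
#' @param view one of `"SAX"`, `"LAX2CH"`, `"LAX4CH"`. LAX stacks must have
#'   exactly one slice.
#' @return an object of class `labelled_stack`.
#' @export
labelled_stack <- function(labels, affine, voxel_size, slice_thickness,
                           slice_gap, frame_times, view) {
  view <- match.arg(view, VALID_VIEWS)
  if (length(dim(labels)) != 4L)
    stop("labels must be a 4-D array (row, col, slice, frame)")
  storage.mode(labels) <- "integer"
  bad <- setdiff(unique(as.vector(labels)), VALID_LABELS)
  if (length(bad) > 0L) {
    n_bad <- sum(labels %in% bad)
    stop(sprintf("unknown label value(s) %s in %d voxel(s)",
                 paste(bad, collapse = ", "), n_bad))
  }
  if (!all(dim(affine) == c(4L, 4L)) || abs(det(affine)) < 1e-12)
    stop("affine must be an invertible 4x4 matrix")
  if (startsWith(view, "LAX") && dim(labels)[3L] != 1L)
    stop("LAX stacks must have exactly 1 slice")
  n_frames <- dim(labels)[4L]
  if (length(frame_times) != n_frames)
    stop("frame_times length must equal number of frames")
  if (frame_times[1L] != 0 || any(diff(frame_times) <= 0))
    stop("frame_times must start at 0 and be strictly increasing")
  structure(list(
    labels = labels,
    affine = affine,
    voxel_size = as.numeric(voxel_size),
    slice_thickness = as.numeric(slice_thickness),
    slice_gap = as.numeric(slice_gap),
    frame_times = as.numeric(frame_times),
    view = view
  ), class = "labelled_stack")
}

#' @export
print.labelled_stack <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<labelled_stack %s: %dx%d in-plane, %d slice(s), %d frame(s)>\n",
              x$view, d[1], d[2], d[3], d[4]))
  invisible(x)
}

n_frames <- function(stack) dim(stack$labels)[4L]
n_slices <- function(stack) dim(stack$labels)[3L]

#' Subject metadata
#'
#' @param sex `"M"`, `"F"` or `"unknown"`.
#' @param age years.
#' @param height cm; required positive when BSA indexing is requested.
#' @param weight kg.
#' @param rr_interval cardiac cycle length in seconds.
#' @return object of class `subject_meta`.
#' @export
subject_meta <- function(sex = "unknown", age = NA_real_, height = NA_real_,
                         weight = NA_real_, rr_interval = 1.0) {
  sex <- match.arg(sex, c("M", "F", "unknown"))
  structure(list(sex = sex, age = age, height = height, weight = weight,
                 rr_interval = rr_interval), class = "subject_meta")
}

#' Assemble a cine study from its three views
#'
#' All views must share the frame count; frame times must agree across views
#' to within 1 ms (LAX times are resampled onto the SAX grid otherwise).
#'
#' @param sax,lax2ch,lax4ch `labelled_stack` objects for the three views.
#' @param subject a [subject_meta()].
#' @param images optional named list of intensity arrays (same dims as the
#'   corresponding label grids) with elements `sax`, `lax2ch`, `lax4ch`.
#' @return object of class `cine_study`.
#' @export
cine_study <- function(sax, lax2ch, lax4ch, subject = subject_meta(),
                       images = NULL) {
  stopifnot(inherits(sax, "labelled_stack"), sax$view == "SAX",
            lax2ch$view == "LAX2CH", lax4ch$view == "LAX4CH")
  nf <- n_frames(sax)
  if (n_frames(lax2ch) != nf || n_frames(lax4ch) != nf)
    stop("all views must share n_frames")
  for (lx in list(lax2ch, lax4ch)) {
    if (max(abs(lx$frame_times - sax$frame_times)) > 1e-3) {
      lx$frame_times <- sax$frame_times  # resample onto common grid
    }
  }
  structure(list(sax = sax, lax2ch = lax2ch, lax4ch = lax4ch,
                 subject = subject, images = images),
            class = "cine_study")
}

#' @export
print.cine_study <- function(x, ...) {
  cat(sprintf("<cine_study: %d frames, %d SAX slices, subject %s age %s>\n",
              n_frames(x$sax), n_slices(x$sax), x$subject$sex,
              format(x$subject$age)), ...)
  invisible(x)
}

#' Voxel index to world coordinates
#'
#' @param stack a `labelled_stack`.
#' @param voxel_index 0-based `(row, col, slice)` triplet, or an `n x 3`
#'   matrix of triplets.
#' @return world point(s) in mm, same shape convention as the input.
#' @export
world_coords <- function(stack, voxel_index) {
  idx <- if (is.matrix(voxel_index)) voxel_index else matrix(voxel_index, 1L)
  d <- dim(stack$labels)
  if (any(idx < 0) || any(idx[, 1] > d[1] - 1) || any(idx[, 2] > d[2] - 1) ||
      any(idx[, 3] > d[3] - 1))
    stop("voxel index out of bounds")
  w <- stack$affine %*% rbind(t(idx), 1)
  out <- t(w[1:3, , drop = FALSE])
  if (is.matrix(voxel_index)) out else drop(out)
}

# world -> continuous 0-based voxel index
voxel_coords <- function(stack, world) {
  w <- if (is.matrix(world)) world else matrix(world, 1L)
  v <- solve(stack$affine) %*% rbind(t(w), 1)
  out <- t(v[1:3, , drop = FALSE])
  if (is.matrix(world)) out else drop(out)
}

unit <- function(v) v / sqrt(sum(v^2))

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Image plane of one slice
#'
#' Returns the world-space plane carrying a given slice: origin (world point of
#' voxel `(0, 0, slice)`), unit normal (perpendicular to both in-plane axes),
#' the in-plane unit axes, and the field-of-view extent in mm.
#'
#' @param stack a `labelled_stack`.
#' @param slice_index 0-based slice index.
#' @return list with `origin`, `normal`, `axes` (2x3, unit row/col axes),
#'   `extent` (mm along row/col).
#' @export
plane_of <- function(stack, slice_index = 0L) {
  d <- dim(stack$labels)
  if (slice_index < 0 || slice_index > d[3] - 1) stop("slice does not exist")
  e_r <- stack$affine[1:3, 1]
  e_c <- stack$affine[1:3, 2]
  origin <- world_coords(stack, c(0, 0, slice_index))
  list(origin = origin,
       normal = unit(cross3(e_r, e_c)),
       axes = rbind(unit(e_r), unit(e_c)),
       extent = c((d[1] - 1) * sqrt(sum(e_r^2)), (d[2] - 1) * sqrt(sum(e_c^2))))
}

#' Intersection line of two image planes
#'
#' Computes the world-space line where two image planes cross, clipped to both
#' fields of view, with an ordered set of sample points along the clipped
#' segment. Returns `NULL` for (near-)parallel planes.
#'
#' @param a,b planes as returned by [plane_of()].
#' @param fov_a,fov_b fields of view; default to the planes' own extents.
#' @param n_samples number of points sampled along the clipped segment.
#' @return list with `line_origin`, `line_direction` (unit), `sample_points`
#'   (`n x 3` matrix), or `NULL` if the planes are parallel or the line misses
#'   either field of view.
#' @export
intersect_planes <- function(a, b, fov_a = a, fov_b = b, n_samples = 200L) {
  d <- cross3(a$normal, b$normal)
  nd <- sqrt(sum(d^2))
  if (nd < 1e-8) return(NULL)
  d <- d / nd
  # point on both planes: least-norm solution of the two plane equations
  A <- rbind(a$normal, b$normal)
  rhs <- c(sum(a$normal * a$origin), sum(b$normal * b$origin))
  p0 <- drop(t(A) %*% solve(A %*% t(A), rhs))

  clip <- function(plane, p0, d) {
    # parameter interval where p0 + t*d lies inside the plane's fov rectangle
    lo <- -Inf; hi <- Inf
    for (k in 1:2) {
      ax <- plane$axes[k, ]
      c0 <- sum((p0 - plane$origin) * ax)
      cd <- sum(d * ax)
      if (abs(cd) < 1e-12) {
        if (c0 < -1e-9 || c0 > plane$extent[k] + 1e-9) return(NULL)
      } else {
        t1 <- (0 - c0) / cd; t2 <- (plane$extent[k] - c0) / cd
        lo <- max(lo, min(t1, t2)); hi <- min(hi, max(t1, t2))
      }
    }
    c(lo, hi)
  }
  ia <- clip(fov_a, p0, d); if (is.null(ia)) return(NULL)
  ib <- clip(fov_b, p0, d); if (is.null(ib)) return(NULL)
  lo <- max(ia[1], ib[1]); hi <- min(ia[2], ib[2])
  if (!is.finite(lo) || !is.finite(hi) || hi <= lo) return(NULL)
  tt <- seq(lo, hi, length.out = n_samples)
  pts <- t(p0 + outer(d, tt))
  list(line_origin = p0, line_direction = d, sample_points = pts)
}

# ---------------------------------------------------------------------------
# Bundle I/O: NIfTI volumes + JSON sidecar

stack_to_nifti <- function(stack) {
  img <- RNifti::asNifti(stack$labels)
  img <- RNifti::`sform<-`(img, structure(stack$affine, code = 2L))
  img
}

view_filename <- c(SAX = "sax.nii.gz", LAX2CH = "lax2ch.nii.gz",
                   LAX4CH = "lax4ch.nii.gz")

#' Write a cine study bundle
#'
#' Serializes a [cine_study()] to a directory: one 4-D NIfTI label volume per
#' view (`sax.nii.gz`, `lax2ch.nii.gz`, `lax4ch.nii.gz`), optional intensity
#' volumes (`*_image.nii.gz`), and a JSON sidecar with timing, geometry and
#' subject metadata.
#'
#' @param study a `cine_study`.
#' @param bundle_path output directory (created if absent).
#' @return `bundle_path`, invisibly.
#' @export
write_study <- function(study, bundle_path) {
  dir.create(bundle_path, recursive = TRUE, showWarnings = FALSE)
  geom <- list()
  for (v in names(view_filename)) {
    key <- tolower(v)
    st <- study[[key]]
    RNifti::writeNifti(stack_to_nifti(st), file.path(bundle_path, view_filename[[v]]))
    if (!is.null(study$images[[key]])) {
      img <- RNifti::asNifti(study$images[[key]])
      img <- RNifti::`sform<-`(img, structure(st$affine, code = 2L))
      RNifti::writeNifti(img, file.path(bundle_path,
                                        sub("\\.nii", "_image.nii", view_filename[[v]])))
    }
    geom[[key]] <- list(voxel_size = st$voxel_size,
                        slice_thickness = st$slice_thickness,
                        slice_gap = st$slice_gap,
                        # full-precision affine (NIfTI srow fields are float32)
                        affine = as.vector(st$affine))
  }
  side <- list(
    rr_interval_s = study$subject$rr_interval,
    trigger_times_s = study$sax$frame_times,
    subject = list(sex = study$subject$sex, age = study$subject$age,
                   height_cm = study$subject$height,
                   weight_kg = study$subject$weight),
    geometry = geom
  )
  jsonlite::write_json(side, file.path(bundle_path, "sidecar.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(bundle_path)
}

#' Read a cine study bundle
#'
#' Inverse of [write_study()]. Validates label values and view presence; if the
#' sidecar carries no per-frame trigger times, uniform spacing
#' `k * RR / n_frames` is assumed.
#'
#' @param bundle_path directory containing the three view volumes and
#'   `sidecar.json`.
#' @return a `cine_study`.
#' @export
read_study <- function(bundle_path) {
  side_path <- file.path(bundle_path, "sidecar.json")
  if (!file.exists(side_path)) stop("missing sidecar.json in ", bundle_path)
  side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
  stacks <- list(); images <- list()
  for (v in names(view_filename)) {
    key <- tolower(v)
    f <- file.path(bundle_path, view_filename[[v]])
    if (!file.exists(f)) {
      f2 <- sub("\\.gz$", "", f)
      if (file.exists(f2)) f <- f2 else stop("missing view ", v)
    }
    img <- RNifti::readNifti(f)
    labels <- as.array(img)
    if (!is.null(side$label_map)) {
      remap <- side$label_map  # named list: stored value -> canonical value
      out <- labels
      for (from in names(remap)) out[labels == as.integer(from)] <- remap[[from]]
      labels <- out
    }
    if (length(dim(labels)) == 3L) dim(labels) <- c(dim(labels), 1L)
    labels <- array(as.integer(labels), dim(labels))
    g <- side$geometry[[key]]
    affine <- if (!is.null(g$affine)) matrix(g$affine, 4L, 4L)
    else matrix(as.vector(RNifti::xform(img)), 4L, 4L)
    nf <- dim(labels)[4L]
    ft <- side$trigger_times_s
    if (is.null(ft) || length(ft) != nf)
      ft <- (seq_len(nf) - 1) * side$rr_interval_s / nf
    stacks[[key]] <- labelled_stack(
      labels = labels, affine = affine,
      voxel_size = g$voxel_size, slice_thickness = g$slice_thickness,
      slice_gap = g$slice_gap, frame_times = ft, view = v)
    fi <- file.path(bundle_path, sub("\\.nii", "_image.nii", view_filename[[v]]))
    if (file.exists(fi)) images[[key]] <- as.array(RNifti::readNifti(fi))
  }
  subj <- subject_meta(
    sex = if (is.null(side$subject$sex)) "unknown" else side$subject$sex,
    age = side$subject$age %||% NA_real_,
    height = side$subject$height_cm %||% NA_real_,
    weight = side$subject$weight_kg %||% NA_real_,
    rr_interval = side$rr_interval_s)
  cine_study(stacks$sax, stacks$lax2ch, stacks$lax4ch, subject = subj,
             images = if (length(images)) images else NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
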