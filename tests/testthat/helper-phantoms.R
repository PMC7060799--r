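# Shared phantom fixtures, built once per test run. Coarse geometry keeps the
# suite fast; accuracy-sensitive checks build their own finer phantoms.

.fixture_env <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- builder()
  .fixture_env[[key]]
}

# 2 mm in-plane, 20 frames: geometry/QC/alignment fixture
coarse_phantom <- function() cached("coarse", function()
  build_phantom(phantom_spec(voxel_size = 2, n_frames = 20)))

# 1.5 mm, 30 frames, with ground-truth displacement fields: strain fixture
field_phantom <- function() cached("field", function()
  build_phantom(phantom_spec(voxel_size = 1.5, n_frames = 30,
                             with_fields = TRUE)))

# a tiny hand-built study (8x8 in-plane) for I/O and timing tests
make_tiny_study <- function(n_frames = 25L, rr = 1.0,
                            trigger_times = NULL) {
  mk_labels <- function(ns) {
    a <- array(0L, c(8, 8, ns, n_frames))
    a[3:6, 3:6, , ] <- 2L
    a[4:5, 4:5, , ] <- 1L
    a
  }
  ft <- trigger_times %||% ((seq_len(n_frames) - 1) * rr / n_frames)
  aff <- diag(4); aff[3, 3] <- 10
  sax <- labelled_stack(mk_labels(3L), aff, c(1, 1), 8, 2, ft, "SAX")
  aff4 <- matrix(0, 4, 4)
  aff4[1, 1] <- 1; aff4[3, 2] <- 1; aff4[2, 3] <- 1; aff4[4, 4] <- 1
  lax4 <- labelled_stack(mk_labels(1L), aff4, c(1, 1), 6, 0, ft, "LAX4CH")
  aff2 <- matrix(0, 4, 4)
  aff2[2, 1] <- 1; aff2[3, 2] <- 1; aff2[1, 3] <- -1; aff2[4, 4] <- 1
  lax2 <- labelled_stack(mk_labels(1L), aff2, c(1, 1), 6, 0, ft, "LAX2CH")
  cine_study(sax, lax2, lax4,
             subject = subject_meta("M", 50, 171, 74, rr))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random well-formed affine (rotation + anisotropic scales + translation)
random_affine <- function() {
  th <- stats::runif(3, 0, 2 * pi)
  rx <- matrix(c(1, 0, 0, 0, cos(th[1]), -sin(th[1]), 0, sin(th[1]), cos(th[1])),
               3, 3, byrow = TRUE)
  rz <- matrix(c(cos(th[3]), -sin(th[3]), 0, sin(th[3]), cos(th[3]), 0, 0, 0, 1),
               3, 3, byrow = TRUE)
  R <- rx %*% rz
  S <- diag(stats::runif(3, 0.8, 3))
  aff <- diag(4)
  aff[1:3, 1:3] <- R %*% S
  aff[1:3, 4] <- stats::runif(3, -50, 50)
  aff
}
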