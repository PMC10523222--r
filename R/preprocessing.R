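#' Pick the upright reference frame
#'
#' The normalization transform is anchored on an early frame in which the
#' subject stands upright. Uprightness is proxied by the projected torso
#' length (Euclidean mid-hip to neck distance), which is longest when the
#' subject is standing straight and facing a level camera: the chosen frame
#' maximizes torso length over the first `window` frames, ties broken by
#' the earliest index.
#'
#' @param seq a [skeleton_sequence()] containing `MidHip` and `Neck`.
#' @param window number of leading frames to search (default 30, about one
#'   second at 30 fps).
#' @return 1-based frame index of the reference frame.
#' @export
choose_reference_frame <- function(seq, window = 30) {
  stopifnot_skeleton(seq)
  if (n_frames(seq) < 1L) stop("empty sequence", call. = FALSE)
  if (window < 1L) stop("window must be >= 1", call. = FALSE)
  w <- seq_len(min(window, n_frames(seq)))
  ok <- seq$conf[w, "MidHip"] > 0 & seq$conf[w, "Neck"] > 0
  if (!any(ok)) {
    stop("no candidate frame with both mid-hip and neck observed in the window",
         call. = FALSE)
  }
  torso <- sqrt((seq$x[w, "Neck"] - seq$x[w, "MidHip"])^2 +
                (seq$y[w, "Neck"] - seq$y[w, "MidHip"])^2)
  torso[!ok] <- -Inf
  unname(which.max(torso))  # first maximum: earliest tie-break
}

#' Compute the hip-centered, torso-scaled normalization
#'
#' From the reference frame, builds the transform `p -> (p + translation) *
#' scale` that maps the mid-hip point to `(0, 0)` and the mid-hip-to-neck
#' (torso) distance to 1. Translation plus isotropic scaling only — no
#' rotation, so postural lean remains visible to the classifier.
#'
#' @param seq a [skeleton_sequence()].
#' @param ref reference frame index from [choose_reference_frame()].
#' @return an object of class `normalization_transform` with fields
#'   `translation` (length-2) and `scale` (positive scalar).
#' @export
compute_normalization <- function(seq, ref) {
  stopifnot_skeleton(seq)
  if (ref < 1L || ref > n_frames(seq)) stop("reference index out of range",
                                            call. = FALSE)
  if (seq$conf[ref, "MidHip"] == 0 || seq$conf[ref, "Neck"] == 0) {
    stop("reference frame must have observed mid-hip and neck", call. = FALSE)
  }
  hip <- c(seq$x[ref, "MidHip"], seq$y[ref, "MidHip"])
  neck <- c(seq$x[ref, "Neck"], seq$y[ref, "Neck"])
  torso <- sqrt(sum((neck - hip)^2))
  if (torso <= .Machine$double.eps) {
    stop("degenerate pose: zero torso length in reference frame", call. = FALSE)
  }
  structure(list(translation = -hip, scale = 1 / torso),
            class = "normalization_transform")
}

#' @export
print.normalization_transform <- function(x, ...) {
  cat(sprintf("<normalization: translate (%+.4g, %+.4g), scale %.6g>\n",
              x$translation[1], x$translation[2], x$scale))
  invisible(x)
}

#' Apply a normalization transform to every frame
#'
#' Maps every joint coordinate in every frame by
#' `p -> (p + translation) * scale`; confidences are untouched. Applied
#' uniformly so that coordinates from subjects of different heights and
#' positions land in a comparable range.
#'
#' @param seq a [skeleton_sequence()].
#' @param t a `normalization_transform` from [compute_normalization()].
#' @return the transformed `skeleton_sequence`.
#' @export
apply_normalization <- function(seq, t) {
  stopifnot_skeleton(seq)
  if (!inherits(t, "normalization_transform")) {
    stop("t must be a normalization_transform", call. = FALSE)
  }
  skeleton_sequence((seq$x + t$translation[1]) * t$scale,
                    (seq$y + t$translation[2]) * t$scale,
                    seq$conf, fps = seq$fps)
}

## Reflect an out-of-range index back into 1..n ("b a | a b c d | d c"
## boundary, period 2n). Used by the Gaussian smoother at sequence edges.
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  j <- (i - 1L) %% (2L * n)
  j <- ifelse(j < 0L, j + 2L * n, j)
  as.integer(ifelse(j < n, j + 1L, 2L * n - j))
}

## Discrete Gaussian kernel, truncated at radius ceiling(4*sigma) and
## renormalized to sum to 1.
gaussian_kernel <- function(sigma) {
  r <- as.integer(ceiling(4 * sigma))
  w <- exp(-((-r:r)^2) / (2 * sigma^2))
  w / sum(w)
}

#' Gaussian-smooth joint trajectories
#'
#' Convolves each joint's x- and y-series independently with a normalized
#' discrete Gaussian kernel (SD `sigma` frames, truncated at radius
#' `ceiling(4*sigma)`, reflected boundaries), suppressing frame-to-frame
#' pose-estimation jitter while leaving the slow squat motion intact.
#' Output length equals input length; confidences pass through.
#'
#' @param seq a [skeleton_sequence()].
#' @param sigma Gaussian SD in frame units (default 1).
#' @return the smoothed `skeleton_sequence`.
#' @export
smooth_sequence <- function(seq, sigma = 1) {
  stopifnot_skeleton(seq)
  if (sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  w <- gaussian_kernel(sigma)
  r <- (length(w) - 1L) %/% 2L
  k <- n_frames(seq)
  sm <- function(m) {
    out <- matrix(0, k, ncol(m), dimnames = dimnames(m))
    for (d in -r:r) {
      out <- out + w[d + r + 1L] * m[reflect_index(seq_len(k) + d, k), , drop = FALSE]
    }
    out
  }
  skeleton_sequence(sm(seq$x), sm(seq$y), seq$conf, fps = seq$fps)
}

#' Per-frame position deltas as the model's feature tensor
#'
#' Row `t` holds `position(frame t+1) - position(frame t)` for the 20
#' coordinates of the 10-joint subset, in fixed channel order
#' (joint-major, x then y). A sequence of `k` frames yields a
#' `(k-1) x 20` matrix; a motionless sequence yields an all-zero matrix.
#'
#' @param seq a [skeleton_sequence()] with exactly the 10 canonical joints,
#'   no missing detections, and at least 2 frames.
#' @return a numeric `(k-1) x 20` matrix of class `feature_tensor` with a
#'   `channels` attribute naming the channel order.
#' @export
delta_features <- function(seq) {
  stopifnot_skeleton(seq)
  jn <- joint_names(seq)
  if (length(jn) != length(SQUAT_JOINTS)) {
    stop(sprintf("schema error: expected a %d-joint sequence, got %d joints; run select_keypoints() first",
                 length(SQUAT_JOINTS), length(jn)), call. = FALSE)
  }
  if (n_frames(seq) < 2L) {
    stop("too-short sequence: delta features need at least 2 frames",
         call. = FALSE)
  }
  if (any(seq$conf == 0)) {
    stop("sequence has missing joints; run interpolate_missing() first",
         call. = FALSE)
  }
  ch <- as.vector(rbind(paste0(jn, "_x"), paste0(jn, "_y")))
  pos <- matrix(0, n_frames(seq), 2L * length(jn),
                dimnames = list(NULL, ch))
  pos[, seq(1L, ncol(pos), by = 2L)] <- seq$x
  pos[, seq(2L, ncol(pos), by = 2L)] <- seq$y
  feats <- diff(pos)
  structure(feats, class = c("feature_tensor", class(feats)), channels = ch)
}

#' Preprocessing settings
#'
#' @param sigma Gaussian smoothing SD in frames (default 1).
#' @param ref_window frames searched for the upright reference (default 30).
#' @param max_missing_frac per-joint missingness tolerance (default 0.2).
#' @param joints joint subset and channel order (default [SQUAT_JOINTS]).
#' @return a list of class `preprocess_config`.
#' @export
preprocess_config <- function(sigma = 1, ref_window = 30,
                              max_missing_frac = 0.2, joints = SQUAT_JOINTS) {
  structure(list(sigma = sigma, ref_window = ref_window,
                 max_missing_frac = max_missing_frac, joints = joints),
            class = "preprocess_config")
}

#' Full preprocessing pipeline: raw keypoints to feature tensor
#'
#' Composes the pipeline: joint subsetting, gap interpolation,
#' hip-centered torso-scaled normalization anchored on an early upright
#' reference frame, Gaussian smoothing, and per-frame differencing. The
#' result is invariant to global translation and uniform scaling of the raw
#' pixel coordinates, but deliberately not to rotation.
#'
#' @param seq a raw [skeleton_sequence()] (any superset of the 10 joints).
#' @param cfg a [preprocess_config()].
#' @return a `(k-1) x 20` `feature_tensor`.
#' @export
preprocess <- function(seq, cfg = preprocess_config()) {
  stopifnot_skeleton(seq)
  if (n_frames(seq) == 0L) stop("empty sequence", call. = FALSE)
  s <- select_keypoints(seq, joints = cfg$joints,
                        max_missing_frac = cfg$max_missing_frac)
  s <- interpolate_missing(s)
  ref <- choose_reference_frame(s, window = cfg$ref_window)
  t <- compute_normalization(s, ref)
  s <- apply_normalization(s, t)
  s <- smooth_sequence(s, sigma = cfg$sigma)
  delta_features(s)
}
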