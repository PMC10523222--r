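#' @keywords internal
"_PACKAGE"

#' Joint vocabularies
#'
#' `BODY25_JOINTS` is the 25-landmark skeleton vocabulary in OpenPose
#' output order. `SQUAT_JOINTS` is the 10-joint torso/leg subset the
#' classifier consumes, in the fixed order that defines the 20-channel
#' feature layout (per joint: x then y).
#'
#' @name joint_vocabularies
#' @export
BODY25_JOINTS <- c(
  "Nose", "Neck", "RShoulder", "RElbow", "RWrist",
  "LShoulder", "LElbow", "LWrist", "MidHip", "RHip",
  "RKnee", "RAnkle", "LHip", "LKnee", "LAnkle",
  "REye", "LEye", "REar", "LEar", "LBigToe",
  "LSmallToe", "LHeel", "RBigToe", "RSmallToe", "RHeel"
)

#' @rdname joint_vocabularies
#' @export
SQUAT_JOINTS <- c(
  "Neck", "MidHip", "LShoulder", "RShoulder", "LHip",
  "RHip", "LKnee", "RKnee", "LAnkle", "RAnkle"
)

#' Construct a skeleton sequence
#'
#' A `skeleton_sequence` holds per-frame 2D keypoints for one person in
#' image coordinates (origin top-left, y grows downward) at a fixed frame
#' rate. Coordinates live in three aligned `frames x joints` matrices
#' (`x`, `y`, `conf`); a joint with confidence 0 is "missing" and its
#' coordinates must be ignored by all downstream computation.
#'
#' @param x,y numeric matrices, frames in rows, joints in columns; column
#'   names are joint identifiers (BODY_25 vocabulary by default).
#' @param conf matrix of detection confidences in `[0, 1]`, same shape.
#' @param fps frames per second (nominal 30).
#' @return an object of class `skeleton_sequence`.
#' @export
skeleton_sequence <- function(x, y, conf = NULL, fps = 30) {
  x <- as.matrix(x)
  y <- as.matrix(y)
  if (is.null(conf)) conf <- matrix(1, nrow(x), ncol(x), dimnames = dimnames(x))
  conf <- as.matrix(conf)
  if (!identical(dim(x), dim(y)) || !identical(dim(x), dim(conf))) {
    stop("x, y and conf must have identical dimensions", call. = FALSE)
  }
  if (is.null(colnames(x))) stop("joint columns must be named", call. = FALSE)
  if (anyDuplicated(colnames(x))) stop("joint names must be unique", call. = FALSE)
  if (!is.numeric(fps) || length(fps) != 1L || fps <= 0) {
    stop("fps must be a single positive number", call. = FALSE)
  }
  if (length(conf) > 0L) {
    cf <- range(conf, na.rm = TRUE)
    if (cf[1] < 0 || cf[2] > 1) stop("confidences must lie in [0, 1]", call. = FALSE)
  }
  colnames(y) <- colnames(conf) <- colnames(x)
  structure(list(x = x, y = y, conf = conf, fps = fps),
            class = "skeleton_sequence")
}

#' @export
print.skeleton_sequence <- function(x, ...) {
  cat(sprintf("<skeleton_sequence: %d frames, %d joints, %g fps>\n",
              nrow(x$x), ncol(x$x), x$fps))
  miss <- mean(x$conf == 0)
  if (miss > 0) cat(sprintf("  missing joint-frames: %.1f%%\n", 100 * miss))
  invisible(x)
}

#' @export
length.skeleton_sequence <- function(x) nrow(x$x)

#' Number of frames in a sequence
#' @param seq a `skeleton_sequence`.
#' @return integer frame count.
#' @export
n_frames <- function(seq) nrow(seq$x)

#' Joint names of a sequence
#' @param seq a `skeleton_sequence`.
#' @return character vector of joint identifiers.
#' @export
joint_names <- function(seq) colnames(seq$x)

stopifnot_skeleton <- function(seq) {
  if (!inherits(seq, "skeleton_sequence")) {
    stop("expected a skeleton_sequence", call. = FALSE)
  }
  invisible(seq)
}

## Position of one joint across frames as an n x 2 matrix (x, y).
joint_xy <- function(seq, joint) {
  cbind(x = seq$x[, joint], y = seq$y[, joint])
}
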