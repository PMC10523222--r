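#' Read 2D pose keypoints from OpenPose-style JSON
#'
#' Two dialects are supported:
#' \describe{
#'   \item{`per_frame_files`}{`path` is a directory holding one JSON file per
#'     frame (the native OpenPose layout), each with
#'     `people[[1]]$pose_keypoints_2d` as a flat `[x, y, c] * 25` list.
#'     Files are taken in lexicographic order; person index 0 only.}
#'   \item{`single_stream`}{`path` is one JSON file containing an array of
#'     frame records `{frame_index, fps, joints: {name: [x, y, c], ...}}` —
#'     the dialect [write_pose_json()] emits.}
#' }
#'
#' A keypoint reported as the `(0, 0, 0)` triple, or with confidence 0, is
#' treated as missing (OpenPose's undetected-joint convention).
#'
#' @param path file or directory, per `dialect`.
#' @param dialect `"per_frame_files"` or `"single_stream"`.
#' @param fps frames per second to stamp on the sequence when the file does
#'   not carry one (per-frame OpenPose files never do). Default 30.
#' @return a [skeleton_sequence()] with gapless frame indices `0..k-1`.
#' @export
read_pose_json <- function(path, dialect = c("single_stream", "per_frame_files"),
                           fps = 30) {
  dialect <- match.arg(dialect)
  if (dialect == "per_frame_files") {
    if (!dir.exists(path)) stop("not a directory: ", path, call. = FALSE)
    files <- sort(list.files(path, pattern = "\\.json$", full.names = TRUE))
    if (length(files) == 0L) stop("empty input: no .json frame files in ", path,
                                  call. = FALSE)
    frames <- lapply(seq_along(files), function(i) {
      rec <- tryCatch(jsonlite::read_json(files[i]),
                      error = function(e) stop(sprintf(
                        "malformed JSON in frame file '%s' (frame %d): %s",
                        files[i], i - 1L, conditionMessage(e)), call. = FALSE))
      if (is.null(rec$people) || length(rec$people) == 0L) {
        return(rep(0, 3L * length(BODY25_JOINTS)))  # nobody detected
      }
      kp <- unlist(rec$people[[1L]]$pose_keypoints_2d)
      if (length(kp) != 3L * length(BODY25_JOINTS)) {
        stop(sprintf("frame file '%s' (frame %d): expected %d keypoint values, got %d",
                     files[i], i - 1L, 3L * length(BODY25_JOINTS), length(kp)),
             call. = FALSE)
      }
      kp
    })
    m <- do.call(rbind, frames)
    idx <- 3L * (seq_along(BODY25_JOINTS) - 1L)
    x <- m[, idx + 1L, drop = FALSE]
    y <- m[, idx + 2L, drop = FALSE]
    cf <- m[, idx + 3L, drop = FALSE]
    colnames(x) <- BODY25_JOINTS
    seq <- skeleton_sequence(x, y, mark_zero_triples(x, y, cf), fps = fps)
    return(seq)
  }

  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  recs <- tryCatch(jsonlite::read_json(path),
                   error = function(e) stop(sprintf(
                     "malformed JSON in '%s': %s", path, conditionMessage(e)),
                     call. = FALSE))
  if (length(recs) == 0L) stop("empty input: '", path, "' has zero frames",
                               call. = FALSE)
  if (!is.null(recs[[1L]]$fps)) fps <- recs[[1L]]$fps
  jn <- names(recs[[1L]]$joints)
  if (is.null(jn)) stop(sprintf("malformed JSON in '%s' frame 0: no named joints",
                                path), call. = FALSE)
  k <- length(recs)
  x <- y <- cf <- matrix(NA_real_, k, length(jn), dimnames = list(NULL, jn))
  ord <- order(vapply(recs, function(r) as.numeric(r$frame_index %||% NA), 0))
  if (all(is.na(ord))) ord <- seq_len(k)
  for (i in seq_len(k)) {
    r <- recs[[ord[i]]]
    for (j in jn) {
      trip <- unlist(r$joints[[j]])
      if (is.null(trip) || length(trip) != 3L) {
        stop(sprintf("malformed JSON in '%s' frame %d: joint '%s' is not an [x,y,c] triple",
                     path, i - 1L, j), call. = FALSE)
      }
      x[i, j] <- trip[1L]; y[i, j] <- trip[2L]; cf[i, j] <- trip[3L]
    }
  }
  skeleton_sequence(x, y, mark_zero_triples(x, y, cf), fps = fps)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## (0,0,0) triples and confidence 0 are equivalent missing-joint markers.
mark_zero_triples <- function(x, y, cf) {
  cf[x == 0 & y == 0 & cf == 0] <- 0
  cf
}

#' Write a skeleton sequence as a single JSON stream
#'
#' Emits the `single_stream` dialect read by [read_pose_json()]: a JSON
#' array of frame records carrying named `[x, y, c]` joint triples plus the
#' frame rate. Coordinates are written with enough digits that a read
#' round-trip reproduces them bit-identically.
#'
#' @param seq a nonempty [skeleton_sequence()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pose_json <- function(seq, path) {
  stopifnot_skeleton(seq)
  if (n_frames(seq) == 0L) stop("cannot write an empty sequence", call. = FALSE)
  jn <- joint_names(seq)
  recs <- lapply(seq_len(n_frames(seq)), function(i) {
    joints <- lapply(jn, function(j) c(seq$x[i, j], seq$y[i, j], seq$conf[i, j]))
    names(joints) <- jn
    list(frame_index = i - 1L, fps = seq$fps, joints = joints)
  })
  txt <- jsonlite::toJSON(recs, auto_unbox = TRUE, digits = I(17))
  ok <- tryCatch({ writeLines(txt, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write to '", path, "'", call. = FALSE)
  invisible(path)
}

#' Restrict a sequence to the 10-joint squat subset
#'
#' Keeps neck, mid-hip, shoulders, hips, knees and ankles (20 coordinates)
#' and drops all other landmarks; arms, head and feet carry little
#' information about squat correctness. Frames where a kept joint was
#' undetected stay marked missing; if any required joint is missing in more
#' than `max_missing_frac` of frames the data are considered too degraded
#' to interpolate and an error is raised.
#'
#' @param seq a [skeleton_sequence()] containing at least the required joints.
#' @param joints character vector of joints to keep; default the canonical
#'   10-joint subset in fixed channel order.
#' @param max_missing_frac per-joint missingness tolerance (default 0.2).
#' @return the restricted `skeleton_sequence`, columns in `joints` order.
#' @export
select_keypoints <- function(seq, joints = SQUAT_JOINTS, max_missing_frac = 0.2) {
  stopifnot_skeleton(seq)
  absent <- setdiff(joints, joint_names(seq))
  if (length(absent) > 0L) {
    stop("required joints absent from input: ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  out <- skeleton_sequence(seq$x[, joints, drop = FALSE],
                           seq$y[, joints, drop = FALSE],
                           seq$conf[, joints, drop = FALSE], fps = seq$fps)
  miss <- colMeans(out$conf == 0)
  bad <- names(miss)[miss > max_missing_frac]
  if (length(bad) > 0L) {
    stop(sprintf(
      "data-quality error: joint(s) %s missing in more than %.0f%% of frames (%s)",
      paste(bad, collapse = ", "), 100 * max_missing_frac,
      paste(sprintf("%s: %.0f%%", bad, 100 * miss[bad]), collapse = ", ")),
      call. = FALSE)
  }
  out
}

#' Fill missing joint detections by linear interpolation
#'
#' Interior gaps are filled linearly between the nearest observed frames;
#' gaps at the head or tail of the sequence copy the nearest observation.
#' Frames where a joint was observed are never altered. Filled joints get
#' confidence equal to the mean confidence of their flanking observations.
#'
#' @param seq a [skeleton_sequence()]; every joint must be observed in at
#'   least one frame.
#' @return a `skeleton_sequence` with no missing joints.
#' @export
interpolate_missing <- function(seq) {
  stopifnot_skeleton(seq)
  if (all(seq$conf > 0)) return(seq)
  k <- n_frames(seq)
  x <- seq$x; y <- seq$y; cf <- seq$conf
  for (j in joint_names(seq)) {
    obs <- which(cf[, j] > 0)
    if (length(obs) == 0L) {
      stop(sprintf("data-quality error: joint '%s' never observed", j),
           call. = FALSE)
    }
    if (length(obs) == k) next
    if (length(obs) == 1L) {
      x[, j] <- x[obs, j]; y[, j] <- y[obs, j]; cf[, j] <- cf[obs, j]
      next
    }
    t_all <- seq_len(k)
    x[, j] <- stats::approx(obs, x[obs, j], xout = t_all, rule = 2)$y
    y[, j] <- stats::approx(obs, y[obs, j], xout = t_all, rule = 2)$y
    cf[, j] <- stats::approx(obs, cf[obs, j], xout = t_all, rule = 2)$y
  }
  skeleton_sequence(x, y, cf, fps = seq$fps)
}
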