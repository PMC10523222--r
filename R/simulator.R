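## Documented defect thresholds: a generated repetition is labeled
## "incorrect" when any of these is exceeded. These are conventions of the
## simulator fixed so that labels are reproducible from coordinates.
DEFECT_THRESHOLDS <- c(
  min_depth_deg   = 70,    # achieved peak knee flexion below this = shallow
  valgus_frac     = 0.15,  # knee medial offset > 15% of hip width at peak
  lean_deg        = 20,    # torso forward tilt beyond this
  asymmetry_deg   = 15     # left/right peak-flexion difference beyond this
)

#' Parameters of a simulated squat repetition
#'
#' Defines a planar two-leg + torso kinematic chain viewed by a frontal
#' camera (image coordinates, y down). The hips descend and rise following
#' a cosine-eased knee-flexion profile that reaches `depth_deg` at
#' mid-repetition. Defect modes perturb the chain:
#' \describe{
#'   \item{`none`}{canonical correct squat (requires `depth_deg >= 70`).}
#'   \item{`shallow_depth`}{achieved depth is `depth_deg * (1 -
#'     defect_magnitude)`; labeled incorrect when the achieved depth falls
#'     below 70 degrees.}
#'   \item{`knee_valgus`}{knees collapse medially by `defect_magnitude *
#'     hip_width`, scaled by instantaneous flexion; incorrect above 0.15.}
#'   \item{`forward_lean`}{torso tilts forward by `defect_magnitude`
#'     degrees at peak flexion, seen frontally as torso foreshortening;
#'     incorrect above 20.}
#'   \item{`asymmetric`}{left/right peak flexion differs by
#'     `defect_magnitude` degrees; incorrect above 15.}
#' }
#'
#' @param torso,thigh,shank,shoulder_width,hip_width segment lengths in
#'   pixels (defaults roughly a person ~600 px tall in frame).
#' @param depth_deg peak knee-flexion angle in degrees (0 = standing).
#' @param tempo_s seconds per repetition.
#' @param n_reps repetitions in the sequence.
#' @param fps frames per second (default 30).
#' @param noise_px SD of per-frame Gaussian jitter on each coordinate.
#' @param defect defect mode, see above.
#' @param defect_magnitude severity; units depend on the mode.
#' @param dropout_prob probability a joint-frame is marked undetected.
#' @param center_x,ground_y image position of the stance (pixels).
#' @param seed RNG seed making the repetition reproducible.
#' @return a validated list of class `squat_sim_params`.
#' @export
squat_sim_params <- function(torso = 200, thigh = 150, shank = 140,
                             shoulder_width = 120, hip_width = 80,
                             depth_deg = 95, tempo_s = 2, n_reps = 1,
                             fps = 30, noise_px = 1,
                             defect = c("none", "shallow_depth", "knee_valgus",
                                        "forward_lean", "asymmetric"),
                             defect_magnitude = 0, dropout_prob = 0,
                             center_x = 640, ground_y = 980, seed = 1L) {
  defect <- match.arg(defect)
  p <- list(torso = torso, thigh = thigh, shank = shank,
            shoulder_width = shoulder_width, hip_width = hip_width,
            depth_deg = depth_deg, tempo_s = tempo_s, n_reps = n_reps,
            fps = fps, noise_px = noise_px, defect = defect,
            defect_magnitude = defect_magnitude, dropout_prob = dropout_prob,
            center_x = center_x, ground_y = ground_y, seed = as.integer(seed))
  lens <- c(torso, thigh, shank, shoulder_width, hip_width)
  if (any(!is.finite(lens)) || any(lens <= 0)) {
    stop("all segment lengths must be positive", call. = FALSE)
  }
  if (depth_deg < 0 || depth_deg > 150) stop("depth_deg must be in [0, 150]",
                                             call. = FALSE)
  if (tempo_s <= 0) stop("tempo_s must be > 0", call. = FALSE)
  if (n_reps < 1) stop("n_reps must be >= 1", call. = FALSE)
  if (noise_px < 0) stop("noise_px must be >= 0", call. = FALSE)
  if (defect_magnitude < 0) stop("defect_magnitude must be >= 0", call. = FALSE)
  if (dropout_prob < 0 || dropout_prob >= 1) stop("dropout_prob must be in [0, 1)",
                                                  call. = FALSE)
  if (defect == "none" && depth_deg < DEFECT_THRESHOLDS[["min_depth_deg"]]) {
    stop(sprintf("defect 'none' requires depth_deg >= %g (a shallower squat is the 'shallow_depth' defect)",
                 DEFECT_THRESHOLDS[["min_depth_deg"]]), call. = FALSE)
  }
  structure(p, class = "squat_sim_params")
}

## Label is a pure function of the parameters, via the documented
## thresholds on the kinematic quantities the defect produces.
squat_label <- function(params) {
  thr <- DEFECT_THRESHOLDS
  bad <- switch(params$defect,
    none          = FALSE,
    shallow_depth = params$depth_deg * (1 - params$defect_magnitude) <
                      thr[["min_depth_deg"]],
    knee_valgus   = params$defect_magnitude > thr[["valgus_frac"]],
    forward_lean  = params$defect_magnitude > thr[["lean_deg"]],
    asymmetric    = params$defect_magnitude > thr[["asymmetry_deg"]]
  )
  if (bad) "incorrect" else "correct"
}

## Run expr with a private RNG stream; the caller's RNG state is untouched.
with_local_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Simulate one labeled squat repetition sequence
#'
#' Generates a full BODY_25 keypoint sequence of a frontal-view squat from
#' a planar kinematic chain: shank and thigh tilt symmetrically about the
#' knee so the hip stays above the ankle, the vertical projections seen by
#' a front camera are `shank*cos(theta/2)` and `thigh*cos(theta/2)` for
#' knee flexion `theta`, and sagittal torso lean appears as torso
#' foreshortening. Additive Gaussian pixel jitter emulates pose-estimator
#' noise. Deterministic given `params$seed`.
#'
#' @param params a [squat_sim_params()].
#' @return a `labeled_sequence`: list with `seq` (a [skeleton_sequence()]),
#'   `label` (`"correct"` or `"incorrect"`), and `params`.
#' @export
simulate_squat <- function(params) {
  if (!inherits(params, "squat_sim_params")) {
    stop("params must come from squat_sim_params()", call. = FALSE)
  }
  p <- params
  k <- max(2L, round(p$n_reps * p$tempo_s * p$fps))
  tt <- (seq_len(k) - 1L) / p$fps
  phase <- (tt %% p$tempo_s) / p$tempo_s          # 0..1 within each rep
  profile <- 0.5 * (1 - cos(2 * pi * phase))      # cosine-eased, peak at 0.5

  depth <- p$depth_deg
  if (p$defect == "shallow_depth") depth <- depth * (1 - p$defect_magnitude)
  asym <- if (p$defect == "asymmetric") p$defect_magnitude else 0
  depth_l <- min(depth + asym / 2, 150)
  depth_r <- max(depth - asym / 2, 0)

  th_l <- depth_l * profile * pi / 180            # left knee flexion (rad)
  th_r <- depth_r * profile * pi / 180
  stance <- 1.1 * p$hip_width

  side <- function(th, sgn) {
    knee_h <- p$shank * cos(th / 2)
    hip_h <- knee_h + p$thigh * cos(th / 2)
    valgus <- if (p$defect == "knee_valgus") {
      p$defect_magnitude * p$hip_width * profile
    } else 0
    list(ankle_x = rep(p$center_x + sgn * stance / 2, k),
         ankle_y = rep(p$ground_y, k),
         knee_x = p$center_x + sgn * stance / 2 - sgn * valgus,
         knee_y = p$ground_y - knee_h,
         hip_x = rep(p$center_x + sgn * p$hip_width / 2, k),
         hip_y = p$ground_y - hip_h)
  }
  L <- side(th_l, -1)   # image x: left body side appears at smaller x
  R <- side(th_r, +1)

  midhip_x <- (L$hip_x + R$hip_x) / 2
  midhip_y <- (L$hip_y + R$hip_y) / 2
  lean <- if (p$defect == "forward_lean") {
    p$defect_magnitude * profile * pi / 180
  } else rep(0, k)
  torso_proj <- p$torso * cos(lean)
  neck_x <- midhip_x
  neck_y <- midhip_y - torso_proj

  xs <- matrix(0, k, length(BODY25_JOINTS),
               dimnames = list(NULL, BODY25_JOINTS))
  ys <- xs
  put <- function(j, x, y) {
    xs[, j] <<- x; ys[, j] <<- y
  }
  put("Neck", neck_x, neck_y)
  put("MidHip", midhip_x, midhip_y)
  put("LShoulder", neck_x - p$shoulder_width / 2, neck_y)
  put("RShoulder", neck_x + p$shoulder_width / 2, neck_y)
  put("LHip", L$hip_x, L$hip_y)
  put("RHip", R$hip_x, R$hip_y)
  put("LKnee", L$knee_x, L$knee_y)
  put("RKnee", R$knee_x, R$knee_y)
  put("LAnkle", L$ankle_x, L$ankle_y)
  put("RAnkle", R$ankle_x, R$ankle_y)
  ## Cosmetic landmarks outside the 10-joint subset, so raw output has the
  ## full BODY_25 shape the pose estimator would produce.
  put("Nose", neck_x, neck_y - 0.25 * torso_proj)
  put("REye", neck_x + 8, neck_y - 0.27 * torso_proj)
  put("LEye", neck_x - 8, neck_y - 0.27 * torso_proj)
  put("REar", neck_x + 16, neck_y - 0.24 * torso_proj)
  put("LEar", neck_x - 16, neck_y - 0.24 * torso_proj)
  arm <- 0.55 * p$torso
  put("LElbow", neck_x - p$shoulder_width / 2 - 6, neck_y + arm / 2)
  put("RElbow", neck_x + p$shoulder_width / 2 + 6, neck_y + arm / 2)
  put("LWrist", neck_x - p$shoulder_width / 2 - 10, neck_y + arm)
  put("RWrist", neck_x + p$shoulder_width / 2 + 10, neck_y + arm)
  foot <- 0.25 * p$shank
  put("LHeel", L$ankle_x, L$ankle_y + 4)
  put("RHeel", R$ankle_x, R$ankle_y + 4)
  put("LBigToe", L$ankle_x + foot / 2, L$ankle_y + 6)
  put("RBigToe", R$ankle_x - foot / 2, R$ankle_y + 6)
  put("LSmallToe", L$ankle_x + foot / 3, L$ankle_y + 6)
  put("RSmallToe", R$ankle_x - foot / 3, R$ankle_y + 6)

  seq <- with_local_seed(p$seed, {
    if (p$noise_px > 0) {
      xs <- xs + matrix(stats::rnorm(length(xs), 0, p$noise_px), k)
      ys <- ys + matrix(stats::rnorm(length(ys), 0, p$noise_px), k)
    }
    conf <- matrix(stats::runif(length(xs), 0.6, 1), k,
                   dimnames = dimnames(xs))
    if (p$dropout_prob > 0) {
      drop <- matrix(stats::runif(length(xs)) < p$dropout_prob, k)
      conf[drop] <- 0
    }
    skeleton_sequence(xs, ys, conf, fps = p$fps)
  })
  structure(list(seq = seq, label = squat_label(p), params = p),
            class = "labeled_sequence")
}

#' @export
print.labeled_sequence <- function(x, ...) {
  cat(sprintf("<labeled_sequence: %s (%s, magnitude %g), %d frames>\n",
              x$label, x$params$defect, x$params$defect_magnitude,
              n_frames(x$seq)))
  invisible(x)
}

#' Simulate a balanced labeled dataset of squat repetitions
#'
#' Emulates a multi-subject recording session: each simulated subject gets
#' its own body proportions (segment lengths scaled by a common factor with
#' small per-segment variation) and camera framing (global position), and
#' contributes repetitions whose depth and tempo vary around the
#' class-level means. Defaults give a clearly separated two-class problem:
#' correct squats at 95 (SD 5) degrees peak flexion versus shallow ones at
#' 45 (SD 5) degrees.
#'
#' @param n_per_class repetitions per class.
#' @param correct_params,incorrect_params named lists overriding the class
#'   recipes: `depth_mean`, `depth_sd`, `defect`, `defect_magnitude`,
#'   `noise_px`, `tempo_mean`, `tempo_sd`, `dropout_prob`.
#' @param n_subjects_per_class simulated subjects per class (default 10);
#'   repetitions are dealt round-robin across subjects.
#' @param fps frames per second.
#' @param seed RNG seed; the dataset is deterministic given it.
#' @return list of `labeled_sequence`, each carrying a `subject_id` field.
#' @export
simulate_dataset <- function(n_per_class,
                             correct_params = list(),
                             incorrect_params = list(),
                             n_subjects_per_class = 10, fps = 30, seed = 1L) {
  if (n_per_class < 1) stop("n_per_class must be >= 1", call. = FALSE)
  cp <- utils::modifyList(list(depth_mean = 95, depth_sd = 5, defect = "none",
                               defect_magnitude = 0, noise_px = 1,
                               tempo_mean = 2, tempo_sd = 0.3,
                               dropout_prob = 0), correct_params)
  ip <- utils::modifyList(list(depth_mean = 45, depth_sd = 5,
                               defect = "shallow_depth", defect_magnitude = 0,
                               noise_px = 1, tempo_mean = 2, tempo_sd = 0.3,
                               dropout_prob = 0), incorrect_params)
  with_local_seed(seed, {
    make_class <- function(recipe, prefix) {
      ns <- min(n_subjects_per_class, n_per_class)
      subjects <- lapply(seq_len(ns), function(s) {
        scale <- stats::runif(1, 0.85, 1.15)
        list(id = sprintf("%s%02d", prefix, s),
             torso = 200 * scale * stats::runif(1, 0.95, 1.05),
             thigh = 150 * scale * stats::runif(1, 0.95, 1.05),
             shank = 140 * scale * stats::runif(1, 0.95, 1.05),
             shoulder_width = 120 * scale * stats::runif(1, 0.92, 1.08),
             hip_width = 80 * scale * stats::runif(1, 0.92, 1.08),
             center_x = 640 + stats::runif(1, -120, 120),
             ground_y = 980 + stats::runif(1, -60, 60))
      })
      lapply(seq_len(n_per_class), function(i) {
        su <- subjects[[(i - 1L) %% ns + 1L]]
        depth <- min(max(stats::rnorm(1, recipe$depth_mean, recipe$depth_sd),
                         5), 150)
        if (recipe$defect == "none") {
          depth <- max(depth, DEFECT_THRESHOLDS[["min_depth_deg"]] + 1)
        }
        tempo <- max(stats::rnorm(1, recipe$tempo_mean, recipe$tempo_sd), 0.8)
        par <- squat_sim_params(
          torso = su$torso, thigh = su$thigh, shank = su$shank,
          shoulder_width = su$shoulder_width, hip_width = su$hip_width,
          depth_deg = depth, tempo_s = tempo, n_reps = 1, fps = fps,
          noise_px = recipe$noise_px, defect = recipe$defect,
          defect_magnitude = recipe$defect_magnitude,
          dropout_prob = recipe$dropout_prob,
          center_x = su$center_x, ground_y = su$ground_y,
          seed = sample.int(.Machine$integer.max, 1))
        out <- simulate_squat(par)
        out$subject_id <- su$id
        out
      })
    }
    c(make_class(cp, "C"), make_class(ip, "S"))
  })
}

#' Split a labeled dataset by simulated subject
#'
#' Assigns whole subjects to the train/validation/test partitions so that
#' no subject's repetitions leak across splits, stratifying by class.
#'
#' @param dataset list of `labeled_sequence` from [simulate_dataset()].
#' @param prop named numeric proportions summing to 1
#'   (default `c(train = 0.6, val = 0.2, test = 0.2)`).
#' @param seed RNG seed for the subject shuffle.
#' @return named list of three datasets: `train`, `val`, `test`.
#' @export
split_by_subject <- function(dataset, prop = c(train = 0.6, val = 0.2, test = 0.2),
                             seed = 1L) {
  if (abs(sum(prop) - 1) > 1e-8) stop("proportions must sum to 1", call. = FALSE)
  subj <- vapply(dataset, function(d) d$subject_id %||% "S00", "")
  lab <- vapply(dataset, function(d) d$label, "")
  subj_lab <- tapply(lab, subj, function(v) v[1])
  with_local_seed(seed, {
    assign_split <- function(ids) {
      ids <- sample(ids)
      n <- length(ids)
      n_tr <- max(1L, round(prop[["train"]] * n))
      n_va <- max(1L, round(prop[["val"]] * n))
      if (n_tr + n_va >= n) n_tr <- max(1L, n - n_va - 1L)
      out <- rep(c("train", "val", "test"), c(n_tr, n_va, n - n_tr - n_va))
      names(out) <- ids
      out
    }
    splits <- unlist(lapply(split(names(subj_lab), subj_lab), assign_split))
    names(splits) <- sub("^[^.]*\\.", "", names(splits))
    part <- splits[subj]
    list(train = dataset[part == "train"],
         val = dataset[part == "val"],
         test = dataset[part == "test"])
  })
}

#' Recover achieved knee flexion from generated coordinates
#'
#' Independent of the simulator's internals: with the hip kept over the
#' ankle, the frontal-view hip height above the ankle is
#' `(thigh + shank) * cos(theta / 2)`, so the peak flexion is
#' `2 * acos(h_min / h_stand)` where heights are read off the coordinates.
#' Used to verify that generated defects are measurable in the data.
#'
#' @param seq a [skeleton_sequence()] containing hips and ankles.
#' @return list with per-side and mean peak knee flexion, in degrees.
#' @export
measure_achieved_depth <- function(seq) {
  stopifnot_skeleton(seq)
  one <- function(hip, ankle) {
    h <- seq$y[, ankle] - seq$y[, hip]   # image y grows downward
    ratio <- min(h) / max(h)
    2 * acos(min(max(ratio, -1), 1)) * 180 / pi
  }
  left <- one("LHip", "LAnkle")
  right <- one("RHip", "RAnkle")
  list(left = left, right = right, mean = (left + right) / 2)
}

#' Measure peak knee medial offset (valgus) from coordinates
#'
#' Reports the maximum inward displacement of each knee from its ankle's
#' vertical line, as a fraction of hip width (distance between hip joints
#' in the first frame).
#'
#' @param seq a [skeleton_sequence()] containing hips, knees and ankles.
#' @return maximum medial offset fraction across sides.
#' @export
measure_valgus <- function(seq) {
  stopifnot_skeleton(seq)
  hip_w <- abs(seq$x[1, "RHip"] - seq$x[1, "LHip"])
  medial_l <- pmax(seq$x[, "LKnee"] - seq$x[, "LAnkle"], 0)   # left knee inward = +x
  medial_r <- pmax(seq$x[, "RAnkle"] - seq$x[, "RKnee"], 0)   # right knee inward = -x
  max(c(medial_l, medial_r)) / hip_w
}

#' Write a labeled dataset to disk
#'
#' Emits one keypoint JSON stream per repetition (the [write_pose_json()]
#' dialect) plus a `labels.csv` manifest with sequence id, label, defect,
#' magnitude, subject and seed.
#'
#' @param dataset list of `labeled_sequence`.
#' @param dir output directory, created if needed.
#' @return path of the manifest, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rows <- lapply(seq_along(dataset), function(i) {
    d <- dataset[[i]]
    id <- sprintf("rep_%04d", i)
    write_pose_json(d$seq, file.path(dir, paste0(id, ".json")))
    data.frame(id = id, label = d$label, defect = d$params$defect,
               magnitude = d$params$defect_magnitude,
               subject = d$subject_id %||% NA_character_,
               seed = d$params$seed, stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  path <- file.path(dir, "labels.csv")
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}
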