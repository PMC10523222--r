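test_that("frame count, determinism and seed sensitivity", {
  p <- squat_sim_params(n_reps = 2, tempo_s = 2, fps = 30, seed = 5)
  a <- simulate_squat(p)
  expect_equal(n_frames(a$seq), 120)             # n_reps * tempo_s * fps
  b <- simulate_squat(p)
  expect_identical(a$seq$x, b$seq$x)             # same seed: bit-identical
  expect_identical(a$seq$y, b$seq$y)
  p2 <- p; p2$seed <- 6L
  c_ <- simulate_squat(p2)
  expect_false(identical(a$seq$x, c_$seq$x))     # distinct seeds: distinct jitter
})

test_that("generated kinematics reproduce the requested knee flexion", {
  for (depth in c(60, 90, 120)) {
    ls1 <- simulate_squat(squat_sim_params(depth_deg = depth, noise_px = 0,
                                           defect = if (depth < 70)
                                             "shallow_depth" else "none",
                                           seed = depth))
    d <- measure_achieved_depth(ls1$seq)
    expect_equal(d$mean, depth, tolerance = 0.5)
    expect_equal(d$left, d$right, tolerance = 0.5)
  }
})

test_that("defect labels are deterministic functions of the parameters", {
  expect_equal(simulate_squat(squat_sim_params(seed = 1))$label, "correct")
  ## shallow: achieved depth below 70 degrees
  expect_equal(simulate_squat(squat_sim_params(defect = "shallow_depth",
                                               depth_deg = 45, seed = 1))$label,
               "incorrect")
  expect_equal(simulate_squat(squat_sim_params(defect = "shallow_depth",
                                               depth_deg = 95,
                                               defect_magnitude = 0.5,
                                               seed = 1))$label, "incorrect")
  expect_equal(simulate_squat(squat_sim_params(defect = "shallow_depth",
                                               depth_deg = 95,
                                               defect_magnitude = 0.1,
                                               seed = 1))$label, "correct")
  ## valgus: medial offset above 15% of hip width
  expect_equal(simulate_squat(squat_sim_params(defect = "knee_valgus",
                                               defect_magnitude = 0.3,
                                               seed = 1))$label, "incorrect")
  expect_equal(simulate_squat(squat_sim_params(defect = "knee_valgus",
                                               defect_magnitude = 0.05,
                                               seed = 1))$label, "correct")
  ## lean and asymmetry thresholds
  expect_equal(simulate_squat(squat_sim_params(defect = "forward_lean",
                                               defect_magnitude = 30,
                                               seed = 1))$label, "incorrect")
  expect_equal(simulate_squat(squat_sim_params(defect = "asymmetric",
                                               defect_magnitude = 25,
                                               seed = 1))$label, "incorrect")
})

test_that("labels agree with defects re-measured from the coordinates", {
  ## shallow squat measured shallow
  sh <- simulate_squat(squat_sim_params(defect = "shallow_depth", depth_deg = 95,
                                        defect_magnitude = 0.55, noise_px = 0,
                                        seed = 2))
  expect_equal(sh$label, "incorrect")
  expect_lt(measure_achieved_depth(sh$seq)$mean, 70)
  ## valgus measured as medial knee travel
  vg <- simulate_squat(squat_sim_params(defect = "knee_valgus",
                                        defect_magnitude = 0.3, noise_px = 0,
                                        seed = 2))
  expect_equal(vg$label, "incorrect")
  expect_gt(measure_valgus(vg$seq), 0.15)
  ok <- simulate_squat(squat_sim_params(noise_px = 0, seed = 2))
  expect_lt(measure_valgus(ok$seq), 0.05)
  ## asymmetry measured as left/right flexion difference
  as_ <- simulate_squat(squat_sim_params(defect = "asymmetric",
                                         defect_magnitude = 25, noise_px = 0,
                                         seed = 2))
  d <- measure_achieved_depth(as_$seq)
  expect_gt(abs(d$left - d$right), 15)
})

test_that("parameter validation rejects out-of-range settings", {
  expect_error(squat_sim_params(depth_deg = 200), "depth_deg")
  expect_error(squat_sim_params(tempo_s = 0), "tempo_s")
  expect_error(squat_sim_params(noise_px = -1), "noise_px")
  expect_error(squat_sim_params(thigh = -5), "positive")
  expect_error(squat_sim_params(defect = "none", depth_deg = 50), "shallow")
})

test_that("simulate_dataset is balanced, deterministic and class-separated", {
  ds <- simulate_dataset(50, seed = 21)
  expect_length(ds, 100)
  labs <- vapply(ds, `[[`, "", "label")
  expect_equal(sum(labs == "correct"), 50)
  expect_equal(sum(labs == "incorrect"), 50)
  ds2 <- simulate_dataset(50, seed = 21)
  expect_identical(lapply(ds, function(d) d$seq$x),
                   lapply(ds2, function(d) d$seq$x))

  ## correct (95 +- 5 deg) vs shallow (45 +- 5 deg): achieved depths of the
  ## two classes are separated by more than 20 degrees pairwise
  depth <- vapply(ds, function(d) measure_achieved_depth(d$seq)$mean, 0)
  expect_gt(min(depth[labs == "correct"]) - max(depth[labs == "incorrect"]), 20)
})

test_that("subject-wise splitting keeps subjects together and differs from a sequence-wise split", {
  ds <- simulate_dataset(40, n_subjects_per_class = 8, seed = 4)
  sp <- split_by_subject(ds, seed = 4)
  expect_named(sp, c("train", "val", "test"))
  expect_equal(sum(lengths(sp)), length(ds))
  subj_of <- function(part) unique(vapply(part, `[[`, "", "subject_id"))
  expect_length(intersect(subj_of(sp$train), subj_of(sp$test)), 0)
  expect_length(intersect(subj_of(sp$train), subj_of(sp$val)), 0)
  ## both classes present in every partition
  for (part in sp) {
    expect_setequal(unique(vapply(part, `[[`, "", "label")),
                    c("correct", "incorrect"))
  }
  ## a sequence-wise 60/20/20 slice of the same data crosses subjects,
  ## so group-wise splitting genuinely changes the test set
  n <- length(ds)
  naive_test <- ds[(n - 15):n]
  expect_true(length(intersect(subj_of(naive_test), subj_of(ds[1:48]))) > 0)
})

test_that("simulated sequences flow through the full pipeline, including dropouts", {
  ds <- simulate_dataset(4, correct_params = list(noise_px = 5, dropout_prob = 0.05),
                         incorrect_params = list(noise_px = 5, dropout_prob = 0.05),
                         seed = 31)
  for (d in ds) {
    ft <- preprocess(d$seq)
    expect_identical(dim(ft), c(n_frames(d$seq) - 1L, 20L))
  }
})

test_that("write_dataset emits per-rep JSON plus a labels manifest", {
  dir <- withr::local_tempdir()
  ds <- simulate_dataset(3, n_subjects_per_class = 3, seed = 8)
  write_dataset(ds, dir)
  manifest <- read.csv(file.path(dir, "labels.csv"))
  expect_equal(nrow(manifest), 6)
  expect_setequal(unique(manifest$label), c("correct", "incorrect"))
  back <- read_pose_json(file.path(dir, "rep_0001.json"))
  expect_identical(unname(back$x), unname(ds[[1]]$seq$x))
})
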