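#' Feedback configuration
#'
#' App-side decision settings: the classification-score cutoff that turns
#' a softmax score into a good/bad verdict (user-adjustable to tune
#' workout difficulty) and the number of repetitions in a scored session.
#'
#' @param threshold score cutoff in `[0, 1]`; default 0.5. A score exactly
#'   at the threshold counts as good.
#' @param session_reps repetitions per scored session; default 10.
#' @return a list of class `feedback_config`.
#' @export
feedback_config <- function(threshold = 0.5, session_reps = 10L) {
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]",
                                           call. = FALSE)
  if (session_reps < 1) stop("session_reps must be >= 1", call. = FALSE)
  structure(list(threshold = threshold, session_reps = as.integer(session_reps)),
            class = "feedback_config")
}

#' Good/bad verdict from a classification score
#'
#' @param score softmax score of the correct-posture class, in `[0, 1]`.
#' @param cfg a [feedback_config()].
#' @return `"good"` if `score >= threshold`, else `"bad"`.
#' @export
verdict <- function(score, cfg = feedback_config()) {
  if (!is.numeric(score) || any(!is.finite(score)) ||
      any(score < 0) || any(score > 1)) {
    stop("score must be a finite number in [0, 1]", call. = FALSE)
  }
  ifelse(score >= cfg$threshold, "good", "bad")
}

#' Score a session of squat repetitions
#'
#' Classifies each repetition and counts the "good" verdicts (the measure
#' used to screen novices: fewer than 3 goods out of 10 repetitions).
#' A repetition that cannot be preprocessed or is too short to classify is
#' counted as bad, with a warning, so a session score always exists.
#'
#' @param seqs list of [skeleton_sequence()], one per repetition.
#' @param model a trained [posture_model].
#' @param cfg a [feedback_config()].
#' @param pp_cfg a [preprocess_config()].
#' @return a `session_score`: list with `n_good`, `n_total`, and `per_rep`
#'   (data frame of score, verdict, note).
#' @export
score_session <- function(seqs, model, cfg = feedback_config(),
                          pp_cfg = preprocess_config()) {
  if (length(seqs) == 0L) stop("empty session", call. = FALSE)
  rows <- lapply(seq_along(seqs), function(i) {
    sc <- tryCatch(classify(model, preprocess(seqs[[i]], pp_cfg)),
                   error = function(e) e)
    if (inherits(sc, "error")) {
      warning(sprintf("repetition %d could not be classified (%s); counted as bad",
                      i, conditionMessage(sc)), call. = FALSE)
      data.frame(rep = i, score = NA_real_, verdict = "bad",
                 note = conditionMessage(sc), stringsAsFactors = FALSE)
    } else {
      data.frame(rep = i, score = sc, verdict = verdict(sc, cfg), note = "",
                 stringsAsFactors = FALSE)
    }
  })
  per_rep <- do.call(rbind, rows)
  structure(list(n_good = sum(per_rep$verdict == "good"),
                 n_total = nrow(per_rep), per_rep = per_rep,
                 threshold = cfg$threshold),
            class = "session_score")
}

#' @export
print.session_score <- function(x, ...) {
  cat(sprintf("session score: %d good out of %d (threshold %.2f)\n",
              x$n_good, x$n_total, x$threshold))
  invisible(x)
}

#' End-to-end pipeline: pose JSON to verdicts and session score
#'
#' Loads one repetition (a single `single_stream` JSON file) or a whole
#' session (a directory of such files, one per repetition), runs
#' preprocessing and the classifier on each, applies the verdict
#' threshold, and returns a deterministic report that fully reconstructs
#' every decision (scores, threshold, config echo). Optionally writes the
#' report as JSON.
#'
#' @param input path to a sequence JSON file or a directory of them.
#' @param model a trained [posture_model] or a checkpoint path.
#' @param cfg a [feedback_config()].
#' @param pp_cfg a [preprocess_config()].
#' @param report_path optional output path for the JSON report.
#' @return list with `session` (a `session_score`), `files`, and `config`.
#' @export
run_pipeline <- function(input, model, cfg = feedback_config(),
                         pp_cfg = preprocess_config(), report_path = NULL) {
  if (is.character(model)) model <- load_model(model)
  files <- if (dir.exists(input)) {
    sort(list.files(input, pattern = "\\.json$", full.names = TRUE))
  } else if (file.exists(input)) {
    input
  } else {
    stop("input not found: ", input, call. = FALSE)
  }
  files <- setdiff(files, file.path(dirname(files), "report.json"))
  if (length(files) == 0L) stop("no sequence JSON files under ", input,
                                call. = FALSE)
  seqs <- lapply(files, read_pose_json, dialect = "single_stream")
  session <- score_session(seqs, model, cfg = cfg, pp_cfg = pp_cfg)
  report <- list(files = basename(files),
                 per_rep = session$per_rep,
                 n_good = session$n_good, n_total = session$n_total,
                 config = list(threshold = cfg$threshold,
                               session_reps = cfg$session_reps,
                               sigma = pp_cfg$sigma,
                               ref_window = pp_cfg$ref_window,
                               variant = model$config$variant,
                               model_seed = model$config$seed))
  if (!is.null(report_path)) {
    jsonlite::write_json(report, report_path, digits = NA, auto_unbox = TRUE)
  }
  c(list(session = session), report["files"], report["config"])
}
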