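#' Extract windowed activity features
#'
#' Slides 1-second windows (200 samples at 200 Hz) with 50% overlap over
#' the recording and computes, per axis: the trapezoidal integral of the
#' accelerometer (a relative velocity-like feature, gravity left in), the
#' trapezoidal integral of the gyroscope (angle), and the energy (sum of
#' squares) of each accelerometer and gyroscope axis — 18 features per
#' window.
#'
#' @param seq an [imu_sequence()] with at least one full window.
#' @param window_s window length in seconds (default 1).
#' @param overlap overlap fraction between consecutive windows (default
#'   0.5).
#' @return A tibble: `start` (sample index of the window) plus 18 feature
#'   columns `vel_{axis}`, `ang_{axis}`, `energy_acc_{axis}`,
#'   `energy_gyr_{axis}`.
#' @export
extract_features <- function(seq, window_s = 1, overlap = 0.5) {
  rate <- imu_rate(seq)
  w <- round(window_s * rate)
  step <- max(1L, round(w * (1 - overlap)))
  n <- nrow(seq)
  if (n < w) {
    abort("sequence shorter than one feature window", class = "ipdr_value_error")
  }
  dt <- 1 / rate
  acc <- imu_acc(seq)
  gyr <- imu_gyr(seq)
  starts <- seq(1L, n - w + 1L, by = step)
  purrr::map_dfr(starts, function(s) {
    ia <- s:(s + w - 1L)
    a <- acc[ia, , drop = FALSE]
    g <- gyr[ia, , drop = FALSE]
    out <- c(
      vel = apply(a, 2, trapz_sum, dt = dt),
      ang = apply(g, 2, trapz_sum, dt = dt),
      energy_acc = colSums(a^2),
      energy_gyr = colSums(g^2))
    names(out) <- paste0(rep(c("vel_", "ang_", "energy_acc_", "energy_gyr_"),
                             each = 3), c("x", "y", "z"))
    tibble::tibble(start = s, !!!as.list(out))
  })
}

trapz_sum <- function(x, dt) dt * (sum(x) - (x[1] + x[length(x)]) / 2)

activity_levels <- c("walk", "jog", "run")

#' Train the activity classifier
#'
#' Support-vector classifier with a third-order polynomial kernel over the
#' 18 window features; features are z-scored internally. Any backend
#' implementing `fit`/`predict` can replace it via the `fit` argument.
#'
#' @param features tibble from [extract_features()] (the `start` column is
#'   ignored).
#' @param labels factor/character of per-window activity labels
#'   (`walk`/`jog`/`run`).
#' @param fit fitting backend: function `(x, y)` returning an object with a
#'   `predict(object, newdata)` method. Default: `e1071::svm`, polynomial
#'   degree 3.
#' @return An object of class `activity_model`.
#' @export
train_activity_model <- function(features, labels, fit = NULL) {
  x <- as.matrix(dplyr::select(features, -dplyr::any_of("start")))
  y <- factor(as.character(labels), levels = activity_levels)
  if (is.null(fit)) {
    # coef0 = 1 gives the usual inhomogeneous polynomial kernel; the
    # homogeneous one (coef0 = 0) separates these z-scored features poorly
    fit <- function(x, y) e1071::svm(x, y, kernel = "polynomial", degree = 3,
                                     coef0 = 1, cost = 10, scale = TRUE)
  }
  structure(list(model = fit(x, y), features = colnames(x)),
            class = "activity_model")
}

#' Classify windows and pick a bout label by majority vote
#'
#' `classify_windows` predicts one activity per feature window;
#' `classify_bout` takes the most frequent prediction, breaking ties
#' toward the slower activity (walk < jog < run).
#'
#' @param model an [train_activity_model()] result.
#' @param features tibble from [extract_features()].
#' @return `classify_windows`: factor of per-window labels;
#'   `classify_bout`: a single label.
#' @export
classify_windows <- function(model, features) {
  if (!inherits(model, "activity_model")) {
    abort("not a trained activity model", class = "ipdr_state_error")
  }
  x <- as.matrix(dplyr::select(features, -dplyr::any_of("start")))
  factor(as.character(predict(model$model, x)), levels = activity_levels)
}

#' @rdname classify_windows
#' @param min_gyr_energy windows whose summed gyroscope energy falls below
#'   this floor ((deg/s)^2, default 1e4, ~3 orders below gait) are treated
#'   as standing still and excluded from the vote; if every window is
#'   static, all windows vote.
#' @export
classify_bout <- function(model, features, min_gyr_energy = 1e4) {
  active <- rowSums(features[, c("energy_gyr_x", "energy_gyr_y",
                                 "energy_gyr_z")]) > min_gyr_energy
  if (!any(active)) active <- rep(TRUE, nrow(features))
  majority_vote(classify_windows(model, features[active, , drop = FALSE]))
}

# most frequent label; ties broken toward the slower activity
majority_vote <- function(labels) {
  counts <- table(factor(labels, levels = activity_levels))
  activity_levels[which.max(counts)]
}

the_activity_model <- new.env(parent = emptyenv())

#' Default activity model trained on synthetic gait
#'
#' Trains the SVM once per session on jittered synthetic bouts of the three
#' activities (fixed seeds) and memoizes it. Accuracies quoted for models
#' trained on real labelled datasets are dataset-bound; this model only
#' discriminates the synthetic stride frequencies/amplitudes.
#'
#' @return An `activity_model`.
#' @export
default_activity_model <- function() {
  if (!is.null(the_activity_model$cache)) return(the_activity_model$cache)
  train <- purrr::map2_dfr(
    rep(activity_levels, each = 6), rep(1:6, times = 3),
    function(a, r) {
      gt <- plan_trajectory(gait_plan(a, n_strides = 12, jitter = 0.1),
                            seed = 100L + r)
      seq <- synthesize_imu(gt, noise_model(0.05, 0.2, seed = 200L + r))
      dplyr::mutate(extract_features(seq), label = a)
    })
  the_activity_model$cache <- train_activity_model(
    dplyr::select(train, -"label"), train$label)
  the_activity_model$cache
}
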