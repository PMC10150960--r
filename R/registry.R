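#' Canonical 83-slot feature registry
#'
#' The ordered list of the 83 numerical predictor variables used to represent
#' one labelled hypoglycemia episode: demographics (3), temporal context (4),
#' interpolated glucose-curve summaries (8), neighbouring SMBG readings (10),
#' neighbouring insulin/carbohydrate intakes with subject-centred amounts (12),
#' bolus-advisor context (6), 90-day self-care statistics for glucose (10,
#' including signed slope means), quick-acting insulin (8), basal insulin (8)
#' and carbohydrates (8), and quiz engagement (6).
#'
#' The raw single-float time-of-day (`tod`) is deliberately *not* part of the
#' canonical vector: its midnight wrap-around makes it a flawed regressor, and
#' the absolute offsets from noon (`cos_tod`) and midnight (`sin_tod`) replace
#' it. `tod` and the three auxiliary advisor fields (`ba_iob`,
#' `ba_allowed_bgv`, `ba_carb_cu`) are carried alongside the canonical vector
#' for single-variable statistics only; see [extra_feature_names()].
#'
#' @return Data frame with columns `name`, `group`, `units`, `missing_allowed`,
#'   exactly 83 rows.
#' @export
feature_registry <- function() {
  reg <- rbind(
    data.frame(name = c("age", "gender", "y_w_diab"),
               group = "demographics", units = c("years", "code", "years"),
               missing_allowed = FALSE),
    data.frame(name = c("cos_tod", "sin_tod", "wake_up_offset", "is_bday"),
               group = "temporal", units = c("hours", "hours", "hours", "flag"),
               missing_allowed = c(FALSE, FALSE, TRUE, FALSE)),
    data.frame(name = paste0("bgi_", c("mean", "std", "range", "min", "max",
                                       "slope", "skew", "kurt")),
               group = "bg_curve",
               units = c(rep("mmol/L", 5), "mmol/L/h", "1", "1"),
               missing_allowed = TRUE),
    data.frame(name = c("pre_g_val", "pre_g_offset", "pre_H_offset", "pre_h_offset",
                        "pre_t_offset", "post_g_val", "post_g_offset", "post_H_offset",
                        "post_h_offset", "post_t_offset"),
               group = "neighbor_bg",
               units = rep(c("mmol/L", rep("hours", 4)), 2),
               missing_allowed = TRUE),
    data.frame(name = c("pre_ins_dosage", "pre_ins_offset", "post_ins_dosage",
                        "post_ins_offset", "pre_bas_dosage", "pre_bas_offset",
                        "post_bas_dosage", "post_bas_offset", "pre_car_dosage",
                        "pre_car_offset", "post_car_dosage", "post_car_offset"),
               group = "intake_context",
               units = rep(c("units", "hours"), 6),
               missing_allowed = TRUE),
    data.frame(name = c("ba_food_ins", "ba_corr_ins", "ba_total_ins", "ba_diff",
                        "ba_meal_rise", "ba_has_excercise"),
               group = "advisor",
               units = c(rep("units", 4), "setting", "flag"),
               missing_allowed = TRUE),
    data.frame(name = c("glu_mean", "glu_std", "glu_range", "glu_max", "glu_min",
                        "glu_mean_x", "glu_skew", "glu_kurt",
                        "neg_slopes_mean", "pos_slopes_mean"),
               group = "longterm_bg",
               units = c(rep("mmol/L", 5), "rate", "1", "1", "mmol/L/h", "mmol/L/h"),
               missing_allowed = TRUE),
    data.frame(name = paste0("ins_", c("mean", "std", "range", "max", "min",
                                       "mean_x", "skew", "kurt")),
               group = "longterm_qa",
               units = c(rep("units", 5), "rate", "1", "1"),
               missing_allowed = TRUE),
    data.frame(name = paste0("bas_", c("mean", "std", "range", "max", "min",
                                       "mean_x", "skew", "kurt")),
               group = "longterm_basal",
               units = c(rep("units", 5), "rate", "1", "1"),
               missing_allowed = TRUE),
    data.frame(name = paste0("car_", c("mean", "std", "range", "max", "min",
                                       "mean_x", "skew", "kurt")),
               group = "longterm_carb",
               units = c(rep("grams", 5), "rate", "1", "1"),
               missing_allowed = TRUE),
    data.frame(name = c("cnc_ansnum", "cnc_daysnum", "cnc_points_avg",
                        "cnc_points_std", "cnc_dist_avg", "cnc_dist_std"),
               group = "quiz",
               units = c("count", "days", "points", "points", "answers", "answers"),
               missing_allowed = c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE))
  )
  stopifnot(nrow(reg) == 83L, !anyDuplicated(reg$name))
  rownames(reg) <- NULL
  reg
}

#' Auxiliary (non-canonical) feature columns
#'
#' `tod` (raw time-of-day fraction) plus the three bolus-advisor settings that
#' accompany the canonical vector in feature tables but are excluded from the
#' 83-slot representation.
#' @return Character vector.
#' @export
extra_feature_names <- function() c("tod", "ba_iob", "ba_allowed_bgv", "ba_carb_cu")

#' Episode-window and horizon configuration for feature extraction
#'
#' @param interp_half_window Half-width in hours of the glucose-interpolation
#'   window centred on the episode (default 3, i.e. a 6-hour segment).
#' @param long_window_days Length in days of the self-care history window
#'   (default 90, i.e. the 3 months preceding the episode).
#' @param hyper_threshold Hyperglycemia threshold in mmol/L (exclusive).
#' @param target_band In-target glucose band in mmol/L (inclusive).
#' @param hypo_threshold Hypoglycemia threshold in mmol/L (exclusive).
#' @param advisor_lookback Advisor lookback window in hours before the episode.
#' @param resample_step_min Resampling step of the interpolated curve, minutes.
#' @return List of class `window_config`.
#' @export
window_config <- function(interp_half_window = 3, long_window_days = 90,
                          hyper_threshold = 10, target_band = c(4, 10),
                          hypo_threshold = 4, advisor_lookback = 6,
                          resample_step_min = 5) {
  stopifnot(interp_half_window > 0, long_window_days > 0, resample_step_min > 0)
  if (!(target_band[1] >= hypo_threshold && target_band[2] <= hyper_threshold)) {
    stop("target_band must lie between the hypo and hyper thresholds", call. = FALSE)
  }
  structure(list(
    interp_half_window = interp_half_window, long_window_days = long_window_days,
    hyper_threshold = hyper_threshold, target_band = target_band,
    hypo_threshold = hypo_threshold, advisor_lookback = advisor_lookback,
    resample_step_min = resample_step_min
  ), class = "window_config")
}
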