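#' Default mapping from raw hypoglycemia reason labels to cause categories
#'
#' The diary interface offers free-text-ish reason labels; analysis groups them
#' into three broad cause families (physical activity, mistakes in food intake,
#' mistakes in medication dosage) plus "Other" and "Don't know". The label
#' vocabulary is site-specific, so the mapping is an ordinary named character
#' vector (label -> category) that callers can replace or extend.
#'
#' @return Named character vector mapping lower-case labels to categories.
#' @export
default_reason_mapping <- function() {
  c(
    "planned exercise"              = "ACTIVITY",
    "unplanned physical activity"   = "ACTIVITY",
    "housework or gardening"        = "ACTIVITY",
    "carbohydrate overestimated"    = "FOOD",
    "missed or delayed meal"        = "FOOD",
    "smaller meal than planned"     = "FOOD",
    "alcohol"                       = "FOOD",
    "too much quick-acting insulin" = "MEDICATION",
    "insulin timing error"          = "MEDICATION",
    "basal dose too high"           = "MEDICATION",
    "other"                         = "OTHER",
    "don't know"                    = "UNKNOWN"
  )
}

#' Map raw reason labels to cause categories
#'
#' Matching is case-insensitive after trimming whitespace. An unmapped label
#' falls into `default` when one is configured, otherwise it is an error naming
#' the offending label.
#'
#' @param raw_reason Character vector of raw labels.
#' @param mapping Named character vector, see [default_reason_mapping()].
#' @param default Optional fallback category for unmapped labels (e.g.
#'   `"OTHER"`); `NULL` (the default) makes unmapped labels an error.
#' @return Character vector of categories, same length as `raw_reason`.
#' @export
map_reason_to_category <- function(raw_reason, mapping = default_reason_mapping(),
                                   default = NULL) {
  stopifnot(is.character(mapping), !is.null(names(mapping)))
  if (!all(mapping %in% hypo_categories())) {
    stop("mapping values must be hypo_categories()", call. = FALSE)
  }
  key <- tolower(trimws(raw_reason))
  out <- unname(mapping[match(key, tolower(trimws(names(mapping))))])
  if (anyNA(out)) {
    if (is.null(default)) {
      bad <- unique(raw_reason[is.na(out)])
      stop("unmapped reason label(s): ", paste(sQuote(bad), collapse = ", "),
           call. = FALSE)
    }
    default <- match.arg(default, hypo_categories())
    out[is.na(out)] <- default
  }
  out
}
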