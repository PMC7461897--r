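# Condition and group vocabularies. The canonical ordering below is used for
# all tie-breaking and output sorting throughout the package.

MM_CONDITIONS <- c(
  "CANCER", "CVD", "HYPERTENSION", "DYSLIPIDEMIA", "DIABETES",
  "ASTHMA", "MENTAL", "NEURODEGEN", "HIP_REPLACEMENT", "OSTEOARTHRITIS"
)

MM_GROUPS <- c("CMD", "CANCER", "ASTHMA", "MENTAL", "NEURODEGEN",
               "MUSCULOSKELETAL")

MM_CONDITION_GROUP <- c(
  CANCER          = "CANCER",
  CVD             = "CMD",
  HYPERTENSION    = "CMD",
  DYSLIPIDEMIA    = "CMD",
  DIABETES        = "CMD",
  ASTHMA          = "ASTHMA",
  MENTAL          = "MENTAL",
  NEURODEGEN      = "NEURODEGEN",
  HIP_REPLACEMENT = "MUSCULOSKELETAL",
  OSTEOARTHRITIS  = "MUSCULOSKELETAL"
)

#' Chronic condition codes
#'
#' The ten chronic conditions tracked by the pipeline, in canonical order.
#' The canonical order is fixed and is used for tie-breaking of same-day
#' onsets and for sorting pattern keys.
#'
#' @return Character vector of length 10.
#' @export
#' @examples
#' condition_codes()
condition_codes <- function() MM_CONDITIONS

#' Condition group codes
#'
#' The six condition groups used for group-level pattern analysis, in
#' canonical order. CMD (cardiometabolic disorder) comprises CVD, diabetes,
#' hypertension and dyslipidemia; MUSCULOSKELETAL comprises hip replacement
#' and osteoarthritis; each remaining condition forms its own group.
#'
#' @return Character vector of length 6.
#' @export
group_codes <- function() MM_GROUPS

#' Map condition codes to group codes
#'
#' @param condition Character vector of condition codes
#'   (see [condition_codes()]).
#' @return Character vector of group codes, same length as `condition`.
#' @export
#' @examples
#' condition_to_group(c("HYPERTENSION", "OSTEOARTHRITIS"))
condition_to_group <- function(condition) {
  bad <- setdiff(unique(condition), MM_CONDITIONS)
  if (length(bad))
    stop("unknown condition code(s): ", paste(bad, collapse = ", "))
  unname(MM_CONDITION_GROUP[condition])
}

check_conditions <- function(condition, what = "condition") {
  bad <- setdiff(unique(as.character(condition)), MM_CONDITIONS)
  if (length(bad))
    stop("unknown ", what, " code(s): ", paste(bad, collapse = ", "))
  invisible(TRUE)
}
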