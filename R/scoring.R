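# Clinical severity scoring: MASI, MASI decline rate, the four-grade efficacy
# classification, and ordinal grading of the five RCM parameters.

#' Facial regions used by the MASI score
#'
#' The four regions of the Melasma Area and Severity Index with their
#' conventional weights: forehead, right malar, left malar at 0.3 each and
#' chin at 0.1.
#'
#' @format Named numeric vector of region weights.
#' @export
masi_region_weights <- c(
  forehead    = 0.3,
  right_malar = 0.3,
  left_malar  = 0.3,
  chin        = 0.1
)

#' Ordered treatment-outcome grades
#'
#' The four efficacy grades, ordered from worst to best. Numeric codes 0-3
#' follow the same order.
#'
#' @format Character vector of grade labels in increasing order.
#' @export
outcome_grades <- c("invalid", "get_better", "effective", "basically_healed")

#' The five RCM parameters scored on the 1-4 ordinal scale
#'
#' @format Character vector of parameter names.
#' @export
rcm_parameters <- c(
  "epidermal_pigmentation", "dendritic_cells", "melanophages",
  "solar_elastosis", "vascularity"
)

#' Melasma Area and Severity Index (MASI)
#'
#' Computes the composite MASI score
#' \deqn{M = 0.3\,A_F(D_F+H_F) + 0.3\,A_{MR}(D_{MR}+H_{MR}) +
#'       0.3\,A_{ML}(D_{ML}+H_{ML}) + 0.1\,A_C(D_C+H_C)}
#' where per region D is darkness (color), H is homogeneity (consistency of
#' color distribution), both integers 0-4, and A is the lesion-area score, an
#' integer 0-6. The attainable range is \[0, 48\].
#'
#' @param regions data.frame with columns `region`, `D`, `H`, `A`; exactly one
#'   row per region named in [masi_region_weights].
#' @return Non-negative scalar MASI score.
#' @examples
#' regions <- data.frame(
#'   region = c("forehead", "right_malar", "left_malar", "chin"),
#'   D = c(2, 0, 0, 0), H = c(1, 0, 0, 0), A = c(3, 0, 0, 0)
#' )
#' masi_score(regions)  # 0.3 * 3 * (2 + 1) = 2.7
#' @export
masi_score <- function(regions) {
  stopifnot(is.data.frame(regions))
  required <- c("region", "D", "H", "A")
  missing_cols <- setdiff(required, names(regions))
  if (length(missing_cols) > 0) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  expected <- names(masi_region_weights)
  if (nrow(regions) != 4L || !setequal(regions$region, expected) ||
      anyDuplicated(regions$region)) {
    stop("need exactly one assessment per region: ",
         paste(expected, collapse = ", "))
  }
  with(regions, {
    if (any(D < 0 | D > 4 | D != round(D))) stop("D must be an integer in 0-4")
    if (any(H < 0 | H > 4 | H != round(H))) stop("H must be an integer in 0-4")
    if (any(A < 0 | A > 6 | A != round(A))) stop("A must be an integer in 0-6")
  })
  w <- masi_region_weights[regions$region]
  sum(w * regions$A * (regions$D + regions$H))
}

#' MASI decline (reduction) rate
#'
#' Relative drop in MASI from before treatment (`value_before`, Vb) to after
#' (`value_after`, Va). The default divides by the pre-treatment baseline,
#' (Vb - Va) / Vb, so that complete clearance gives 1 and the four grade bands
#' of [grade_outcome] are attainable. `denominator = "after"` divides by Va
#' instead, for comparison with formulations that normalize by the
#' post-treatment value.
#'
#' @param value_before Non-negative MASI before treatment; must be > 0 for the
#'   default denominator.
#' @param value_after Non-negative MASI after treatment.
#' @param denominator `"before"` (default) or `"after"`.
#' @return Decline rate as a fraction; negative when the score worsened.
#' @examples
#' masi_decline_rate(20, 2)   # 0.90
#' masi_decline_rate(16, 4)   # 0.75
#' @export
masi_decline_rate <- function(value_before, value_after,
                              denominator = c("before", "after")) {
  denominator <- match.arg(denominator)
  stopifnot(is.numeric(value_before), is.numeric(value_after))
  if (any(value_before < 0) || any(value_after < 0)) {
    stop("MASI values must be non-negative")
  }
  denom <- if (denominator == "before") value_before else value_after
  if (any(denom == 0)) {
    stop("undefined baseline: denominator MASI value is 0")
  }
  (value_before - value_after) / denom
}

#' Classify a MASI decline rate into the four-grade efficacy scale
#'
#' Bands (half-open so every finite rate is classified):
#' rate >= 0.90 is `basically_healed`; \[0.50, 0.90) is `effective`;
#' \[0.10, 0.50) is `get_better`; below 0.10 is `invalid`.
#'
#' @param decline_rate Numeric vector of decline rates (fractions).
#' @return Ordered factor with levels [outcome_grades].
#' @examples
#' grade_outcome(c(0.95, 0.60, 0.05))
#' @export
grade_outcome <- function(decline_rate) {
  if (!is.numeric(decline_rate) || any(!is.finite(decline_rate))) {
    stop("decline_rate must be finite numeric")
  }
  idx <- findInterval(decline_rate, c(0.10, 0.50, 0.90)) + 1L
  factor(outcome_grades[idx], levels = outcome_grades, ordered = TRUE)
}

#' Numeric code of an outcome grade
#'
#' Bijection between the ordered grade labels and integer codes 0-3.
#'
#' @param grade Ordered factor or character vector of grade labels.
#' @return Integer vector in 0-3.
#' @export
grade_code <- function(grade) {
  m <- match(as.character(grade), outcome_grades)
  if (anyNA(m)) stop("unknown grade label")
  m - 1L
}

#' Ordinal RCM grading of one parameter (1-4 scale)
#'
#' Maps a raw reflectance-confocal-microscopy measurement onto the 1-4 scoring
#' column for its parameter:
#' \itemize{
#'   \item `epidermal_pigmentation` — fraction of the field pigmented, in
#'     \[0,1\]: <= 0.25 scores 1, (0.25, 0.50\] scores 2, (0.50, 0.75\] scores
#'     3, above 0.75 scores 4.
#'   \item `dendritic_cells` — count per field: 0 scores 1, 1-5 scores 2,
#'     6-15 scores 3, more than 15 scores 4.
#'   \item `melanophages` — count per field: 0 scores 1, 1-5 scores 2, 6-10
#'     scores 3, more than 10 scores 4.
#'   \item `solar_elastosis`, `vascularity` — severity label
#'     `normal`/`mild`/`moderate`/`serious` mapping to 1/2/3/4.
#' }
#'
#' @param parameter One of [rcm_parameters].
#' @param measurement Numeric fraction, non-negative count, or severity label,
#'   matching the parameter.
#' @return Integer score in 1-4.
#' @examples
#' rcm_grade("epidermal_pigmentation", 0.30)  # 2
#' rcm_grade("melanophages", 12)              # 4
#' @export
rcm_grade <- function(parameter, measurement) {
  parameter <- match.arg(parameter, rcm_parameters)
  if (parameter == "epidermal_pigmentation") {
    if (!is.numeric(measurement) || measurement < 0 || measurement > 1) {
      stop("pigmentation fraction must be in [0, 1]")
    }
    return(findInterval(measurement, c(0.25, 0.50, 0.75), left.open = TRUE) + 1L)
  }
  if (parameter %in% c("dendritic_cells", "melanophages")) {
    if (!is.numeric(measurement) || measurement < 0) {
      stop("cell count must be a non-negative number")
    }
    cuts <- if (parameter == "dendritic_cells") c(0, 5, 15) else c(0, 5, 10)
    return(findInterval(measurement, cuts, left.open = TRUE) + 1L)
  }
  severity <- c(normal = 1L, mild = 2L, moderate = 3L, serious = 4L)
  m <- as.character(measurement)
  if (!m %in% names(severity)) {
    stop("severity must be one of: ", paste(names(severity), collapse = ", "))
  }
  unname(severity[m])
}

#' Continuous network target for an outcome grade
#'
#' Encodes each grade at the midpoint of its decline-rate band:
#' invalid 0.05, get_better 0.30, effective 0.70, basically_healed 0.95.
#' The encoding is strictly increasing in grade order, and [grade_outcome]
#' inverts it (each midpoint falls inside its own band).
#'
#' @param grade Ordered factor or character vector of grade labels.
#' @return Numeric vector in \[0, 1\].
#' @export
grade_to_target <- function(grade) {
  enc <- c(invalid = 0.05, get_better = 0.30, effective = 0.70,
           basically_healed = 0.95)
  m <- match(as.character(grade), outcome_grades)
  if (anyNA(m)) stop("unknown grade label")
  unname(enc[m])
}
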