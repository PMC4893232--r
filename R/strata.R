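# stratification rules: sampling period and land-use classification

#' Assign the sampling period of a collection date
#'
#' The survey year is split into an early period (January--June) and a late
#' period (July--December); only the month matters.
#'
#' @param date a `Date` vector (or anything `as.Date()` accepts).
#' @return character vector, `"early"` or `"late"`.
#' @examples
#' assign_period(as.Date(c("2014-06-15", "2014-07-01")))
#' @export
assign_period <- function(date) {
  date <- as.Date(date)
  if (anyNA(date)) stop("invalid date(s) passed to assign_period")
  month <- as.integer(format(date, "%m"))
  ifelse(month <= 6L, "early", "late")
}

#' Aggregate a Corine land-cover class code into a land-use class
#'
#' Corine Land Cover level-3 class codes are collapsed into three aggregate
#' land-use classes: artificial surfaces (111--142) are `"urban"`,
#' agricultural areas (211--244) are `"rural"`, and forest/semi-natural,
#' wetland and water classes (311--423) are `"natural"`.
#'
#' @param class_code integer vector of Corine class codes.
#' @return character vector of land-use classes.
#' @examples
#' aggregate_corine(c(112, 231, 311))
#' @export
aggregate_corine <- function(class_code) {
  class_code <- as.integer(class_code)
  out <- rep(NA_character_, length(class_code))
  out[class_code >= 111L & class_code <= 142L] <- "urban"
  out[class_code >= 211L & class_code <= 244L] <- "rural"
  out[class_code >= 311L & class_code <= 423L] <- "natural"
  if (anyNA(out)) {
    bad <- unique(class_code[is.na(out)])
    stop("unclassified Corine code(s): ", paste(bad, collapse = ", "))
  }
  out
}

#' Classify a site's land use from aggregate land-cover proportions
#'
#' A site is classified by the dominant aggregate land-cover class in its
#' surrounding buffer. An exact tie for the maximum is an error unless a
#' deterministic fallback is requested, in which case the tie is broken in
#' the fixed order urban > rural > natural.
#'
#' @param proportions named numeric vector with entries `urban`, `rural`,
#'   `natural`; non-negative, summing to at most 1 (plus tolerance).
#' @param tie_break if `TRUE`, break exact ties by the fixed preference
#'   order instead of raising an error.
#' @return one of `"urban"`, `"rural"`, `"natural"`.
#' @examples
#' classify_land_use(c(urban = 0.1, rural = 0.7, natural = 0.2))
#' @export
classify_land_use <- function(proportions, tie_break = FALSE) {
  miss <- setdiff(LAND_USES, names(proportions))
  if (length(miss) > 0) {
    stop("proportions are missing class(es): ", paste(miss, collapse = ", "))
  }
  p <- as.numeric(proportions[LAND_USES])
  if (any(p < 0)) stop("land-cover proportions must be non-negative")
  if (sum(p) > 1 + 1e-8) stop("land-cover proportions sum to more than 1")
  top <- which(p == max(p))
  if (length(top) > 1 && !tie_break) {
    stop("exact tie between land-use classes: ",
         paste(LAND_USES[top], collapse = ", "),
         " (set tie_break = TRUE for the fixed urban > rural > natural order)")
  }
  LAND_USES[top[1L]]
}
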