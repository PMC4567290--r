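#' Discriminant-function coefficients
#'
#' Fixed factor loadings of the four-measurement linear discriminant used to
#' separate Africanized from European workers: one set for individual workers,
#' one for colony means (means of each measurement taken first, typically over
#' ten workers). Measurements are lengths in millimetres of the right forewing
#' (FWL), right hindwing (HWL), and the femur (FL) and tibia (TL) of the right
#' hind leg.
#'
#' @param formula `"individual"` or `"colony_mean"`.
#' @return A list with `weights` (named numeric vector over FWL, HWL, FL, TL)
#'   and `constant`.
#' @export
#' @examples
#' discriminant_coefficients("individual")$weights
discriminant_coefficients <- function(formula = c("individual", "colony_mean")) {
  formula <- match.arg(formula)
  switch(formula,
    individual = list(
      weights = c(FWL = 2.5164, HWL = 1.2159, FL = 16.3439, TL = -10.6356),
      constant = -36.4909
    ),
    colony_mean = list(
      weights = c(FWL = 2.7535, HWL = 2.6834, FL = 27.9261, TL = -19.5551),
      constant = -46.5884
    )
  )
}

.check_measurements <- function(fwl, hwl, femur, tibia) {
  vals <- c(fwl, hwl, femur, tibia)
  if (any(!is.finite(vals))) {
    stop("morphometric measurements must be finite numbers", call. = FALSE)
  }
  if (any(vals < 0.5 | vals > 20)) {
    warning("measurement outside plausibility bounds [0.5, 20] mm", call. = FALSE)
  }
  invisible(NULL)
}

#' Individual-worker discriminant score
#'
#' Applies the individual-worker loadings to the four measurements of a single
#' worker. Scores below the configured midpoint indicate Africanization.
#' Vectorised over workers.
#'
#' @param fwl,hwl,femur,tibia Lengths in mm (forewing, hindwing, femur, tibia).
#' @param check Validate plausibility bounds (warn outside 0.5-20 mm). Set to
#'   `FALSE` only for numeric experiments; non-finite inputs always error.
#' @return Numeric vector of scores at full floating precision.
#' @export
#' @examples
#' individual_score(9.0, 6.0, 2.6, 3.2)
individual_score <- function(fwl, hwl, femur, tibia, check = TRUE) {
  n <- length(fwl)
  if (length(hwl) != n || length(femur) != n || length(tibia) != n) {
    stop("measurement vectors must have equal length", call. = FALSE)
  }
  if (any(!is.finite(c(fwl, hwl, femur, tibia)))) {
    stop("morphometric measurements must be finite numbers", call. = FALSE)
  }
  if (check) .check_measurements(fwl, hwl, femur, tibia)
  co <- discriminant_coefficients("individual")
  w <- co$weights
  w[["FWL"]] * fwl + w[["HWL"]] * hwl + w[["FL"]] * femur + w[["TL"]] * tibia +
    co$constant
}

#' Colony-mean discriminant score
#'
#' Averages each measurement across the sampled workers of one colony, then
#' applies the colony-mean loadings to the means. The reference protocol uses
#' ten workers per colony; other sizes are accepted with a warning.
#'
#' @param fwl,hwl,femur,tibia Numeric vectors of per-worker lengths (mm), one
#'   element per sampled worker of the colony.
#' @param check Validate plausibility bounds as in [individual_score()].
#' @return A single score.
#' @export
colony_score <- function(fwl, hwl, femur, tibia, check = TRUE) {
  n <- length(fwl)
  if (n == 0L) stop("colony_score requires at least one worker", call. = FALSE)
  if (length(hwl) != n || length(femur) != n || length(tibia) != n) {
    stop("measurement vectors must have equal length", call. = FALSE)
  }
  if (any(!is.finite(c(fwl, hwl, femur, tibia)))) {
    stop("morphometric measurements must be finite numbers", call. = FALSE)
  }
  if (check) .check_measurements(fwl, hwl, femur, tibia)
  if (n != 10L) {
    warning(sprintf("colony score computed from %d workers (protocol uses 10)", n),
            call. = FALSE)
  }
  co <- discriminant_coefficients("colony_mean")
  w <- co$weights
  w[["FWL"]] * mean(fwl) + w[["HWL"]] * mean(hwl) + w[["FL"]] * mean(femur) +
    w[["TL"]] * mean(tibia) + co$constant
}

#' Classify discriminant scores against a midpoint threshold
#'
#' A score strictly below the threshold is classified `africanized`; a score
#' equal to or above it is `european` (ties deliberately resolve to european,
#' the conservative direction). The discriminant axes are constructed so the
#' group means straddle zero, hence the shipped default threshold of 0;
#' reproducing a specific study's cutoffs requires supplying the midpoint
#' between its reference group means.
#'
#' @param score Numeric vector of discriminant scores.
#' @param formula Which formula produced the scores (recorded in the result).
#' @param threshold Midpoint; defaults to 0 for either formula.
#' @return A tibble with columns `score`, `formula`, `classification`,
#'   `threshold_used`.
#' @export
#' @examples
#' classify_score(c(-0.3, 0, 1.2))
classify_score <- function(score, formula = c("individual", "colony_mean"),
                           threshold = NULL) {
  formula <- match.arg(formula)
  if (any(!is.finite(score))) stop("scores must be finite", call. = FALSE)
  if (is.null(threshold)) threshold <- 0
  stopifnot(is.numeric(threshold), length(threshold) == 1L, is.finite(threshold))
  tibble::tibble(
    score = as.numeric(score),
    formula = formula,
    classification = ifelse(score < threshold, "africanized", "european"),
    threshold_used = threshold
  )
}

#' Score a measurement table
#'
#' Convenience wrapper over [individual_score()], [colony_score()] and
#' [classify_score()] for tables produced by [read_measurements()]. With
#' `group_by` set, measurements are averaged within groups and scored with the
#' colony-mean formula; otherwise every row is scored individually.
#'
#' @param measurements Data frame with columns `FWL`, `HWL`, `FL`, `TL` (mm).
#' @param group_by Optional column name (e.g. `"colony_id"`) for colony means.
#' @param threshold Midpoint passed to [classify_score()].
#' @return Input identifiers plus `score`, `classification`, `threshold_used`.
#' @export
score_measurements <- function(measurements, group_by = NULL, threshold = NULL) {
  need <- c("FWL", "HWL", "FL", "TL")
  miss <- setdiff(need, names(measurements))
  if (length(miss)) {
    stop("missing measurement column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(group_by)) {
    sc <- individual_score(measurements$FWL, measurements$HWL,
                           measurements$FL, measurements$TL)
    res <- classify_score(sc, "individual", threshold)
    dplyr::bind_cols(
      measurements[intersect(c("specimen_id", "site_id"), names(measurements))],
      res
    )
  } else {
    if (!group_by %in% names(measurements)) {
      stop("grouping column not found: ", group_by, call. = FALSE)
    }
    grps <- split(measurements, measurements[[group_by]])
    sc <- vapply(grps, function(g) {
      colony_score(g$FWL, g$HWL, g$FL, g$TL)
    }, numeric(1))
    res <- classify_score(unname(sc), "colony_mean", threshold)
    dplyr::bind_cols(tibble::tibble(!!group_by := names(grps)), res)
  }
}
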