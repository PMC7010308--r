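#' Wood density from branch measurements
#'
#' Density of a branch section is oven-dry weight over dry volume (g/cm^3);
#' the species value is the mean over its measured branches.
#'
#' @param species character vector of host labels (one entry per branch).
#' @param dry_weight oven-dry weight in g (>= 0).
#' @param dry_volume dry volume in cm^3 (> 0, by water displacement).
#' @return named numeric vector of per-species mean densities.
#' @examples
#' wood_density("sp1", 15, 20)  # 0.75
#' @export
wood_density <- function(species, dry_weight, dry_volume) {
  if (any(dry_volume <= 0)) stop("dry volume must be positive")
  if (any(dry_weight < 0)) stop("dry weight must be non-negative")
  if (any(dry_weight == 0))
    warning("zero dry weight measurement(s): density 0")
  tapply(dry_weight / dry_volume, species, mean)[unique(species)]
}

#' Percent daily decomposition (PDD) of wood
#'
#' Percent mass lost per day of field exposure:
#' `100 * ((initial - final) / initial) / days`, averaged per species.  A
#' final weight above the initial (e.g. moisture uptake) yields a negative
#' value, which is kept but flagged with a warning.  `literal = TRUE`
#' computes percent mass *remaining* per day
#' (`100 * (1 - (initial - final)/initial) / days`) instead.
#'
#' @param species character vector of host labels (one entry per branch).
#' @param initial_weight,final_weight branch weights in g.
#' @param exposure_days days of field exposure (> 0).
#' @param literal use the mass-remaining variant (default `FALSE`).
#' @return named numeric vector of per-species mean PDD (percent/day).
#' @examples
#' pdd("sp1", 100, 80, 200)  # 0.1 %/day
#' @export
pdd <- function(species, initial_weight, final_weight, exposure_days,
                literal = FALSE) {
  if (any(initial_weight <= 0)) stop("initial weight must be positive")
  if (any(exposure_days <= 0)) stop("exposure days must be positive")
  loss <- (initial_weight - final_weight) / initial_weight
  if (any(loss < 0))
    warning("weight gain in ", sum(loss < 0),
            " measurement(s): negative PDD retained")
  val <- if (literal) 100 * (1 - loss) / exposure_days
         else 100 * loss / exposure_days
  tapply(val, species, mean)[unique(species)]
}

#' Body-size index (BSI) of beetles
#'
#' Per individual, body length times body width (mm^2); the species value is
#' the mean over measured individuals.
#'
#' @param species character vector of beetle labels (one entry per
#'   individual).
#' @param length_mm,width_mm body dimensions in mm (> 0).
#' @return named numeric vector of per-species mean BSI (mm^2).
#' @examples
#' bsi("sp1", 10, 3)  # 30
#' @export
bsi <- function(species, length_mm, width_mm) {
  if (any(length_mm <= 0) || any(width_mm <= 0))
    stop("body dimensions must be positive")
  tapply(length_mm * width_mm, species, mean)[unique(species)]
}
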