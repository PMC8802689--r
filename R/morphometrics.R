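# Derived pinna morphometrics.

#' Effective pinna diameter
#'
#' Geometric mean of pinna length and width:
#' `sqrt(pinna_length * pinna_width)` (mm).  Symmetric in its arguments and
#' bounded between them; homogeneous of degree one.  Inputs are accepted at
#' caliper resolution (0.01 mm) or finer; derived values are not rounded.
#'
#' @param pinna_width_mm,pinna_length_mm caliper measurements in mm; must
#'   be positive.
#' @return effective diameter in mm (vectorized).
#' @export
effective_diameter <- function(pinna_width_mm, pinna_length_mm) {
  if (!is.numeric(pinna_width_mm) || !is.numeric(pinna_length_mm) ||
      any(!is.finite(pinna_width_mm)) || any(!is.finite(pinna_length_mm)) ||
      any(pinna_width_mm <= 0) || any(pinna_length_mm <= 0)) {
    stop("pinna dimensions must be positive and finite (mm)", call. = FALSE)
  }
  sqrt(pinna_length_mm * pinna_width_mm)
}

#' Morphology table with derived measures
#'
#' Validates a per-animal morphology table and appends the effective
#' diameter column.
#'
#' @param morphology data frame with columns `animal`, `sex`, `genotype`,
#'   `pinna_width_mm`, `pinna_length_mm`, `interpinna_mm`,
#'   `nose_to_pinna_mm`, `weight_g`.
#' @return the table with `effective_diameter_mm` added.
#' @export
morphology_table <- function(morphology) {
  required <- c("animal", "sex", "genotype", "pinna_width_mm",
                "pinna_length_mm", "interpinna_mm", "nose_to_pinna_mm",
                "weight_g")
  missing <- setdiff(required, names(morphology))
  if (length(missing)) {
    stop("morphology table lacks columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  lengths <- c("pinna_width_mm", "pinna_length_mm", "interpinna_mm",
               "nose_to_pinna_mm")
  if (any(as.matrix(morphology[lengths]) <= 0)) {
    stop("all morphological lengths must be positive", call. = FALSE)
  }
  morphology$effective_diameter_mm <-
    effective_diameter(morphology$pinna_width_mm, morphology$pinna_length_mm)
  morphology
}
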