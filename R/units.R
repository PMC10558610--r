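#' Convert a biomarker concentration between mmol/l and mg/dl
#'
#' Concentrations arrive from surveys in either molar (mmol/l) or mass
#' (mg/dl) units depending on the instrument. All lipid/glucose formulas in
#' this package expect mg/dl except LAP and VAI, which convert triglycerides
#' and HDL back to mmol/l internally. Molar masses differ by analyte, so the
#' analyte class must be named explicitly; guessing from magnitude is refused.
#'
#' Conversion constants (mg/dl per mmol/l): glucose 18.016, the cholesterol
#' family (total, HDL, LDL) 38.67, triglycerides 88.57.
#'
#' @param value numeric vector of non-negative concentrations.
#' @param analyte one of `"glucose"`, `"cholesterol"` (total/HDL/LDL) or
#'   `"triglycerides"`.
#' @param from,to unit tags, each `"mmol/l"` or `"mg/dl"`.
#' @return numeric vector in the target unit. Converting to the same unit is
#'   the identity; the round trip is the identity to better than 1e-9 relative.
#' @examples
#' convert_concentration(5, "glucose", "mmol/l", "mg/dl")   # 90.08
#' convert_concentration(88.57, "triglycerides", "mg/dl", "mmol/l")  # 1
#' @export
convert_concentration <- function(value, analyte, from, to) {
  constants <- c(glucose = 18.016, cholesterol = 38.67, triglycerides = 88.57)
  if (length(analyte) != 1L || !analyte %in% names(constants)) {
    stop("unknown analyte '", paste(analyte, collapse = ","),
         "'; expected one of: ", paste(names(constants), collapse = ", "))
  }
  units <- c("mmol/l", "mg/dl")
  if (length(from) != 1L || !from %in% units) stop("unknown unit '", from, "'")
  if (length(to) != 1L || !to %in% units) stop("unknown unit '", to, "'")
  if (any(value < 0, na.rm = TRUE)) stop("concentrations must be non-negative")
  k <- constants[[analyte]]
  if (from == to) return(value)
  if (from == "mmol/l") value * k else value / k
}
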