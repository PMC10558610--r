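# Derived anthropometric and biomarker indices.
#
# All functions are vectorised over rows of a records data.frame whose
# columns use the canonical field names (see measured_fields()): heights and
# circumferences in cm, weight in kg, concentrations in mg/dl. Heights are
# converted to metres inside formulas where the definition demands it.
# Missing inputs propagate as NA ("unavailable"); values that are computable
# but physiologically out of range (negative LAP or LDL, BF% outside 0-100)
# are retained, never zero-filled.

index_variants <- function(whtr_conventional = FALSE, friedewald_ldl = FALSE,
                           rfm_as_printed = FALSE) {
  list(whtr_conventional = isTRUE(whtr_conventional),
       friedewald_ldl = isTRUE(friedewald_ldl),
       rfm_as_printed = isTRUE(rfm_as_printed))
}

col_or_na <- function(q, nm, n = NULL) {
  if (!is.null(q[[nm]])) return(q[[nm]])
  rep(NA_real_, if (is.null(n)) nrow(as.data.frame(q)) else n)
}

guard_pos <- function(x) ifelse(!is.na(x) & x > 0, x, NA_real_)

#' Mass-ratio indices: BMI, PI, RPI, BI, WHR, WWI, WHT.5R, WHtR
#'
#' BMI = W/H(m)^2; ponderal index PI = W/H(m)^3; reciprocal ponderal index
#' RPI = H(m)/W^(1/3); Broca index BI = H(cm) - 100; WHR = WC/HC;
#' weight-adjusted waist index WWI = WC(cm)/sqrt(W); WHT.5R = WC(cm)/sqrt(H(cm)).
#' WHtR defaults to WC(m)/H(m)^2 (the survey-table convention this package
#' reproduces, magnitudes ~0.35); set `variants$whtr_conventional` for the
#' textbook WC/H.
#'
#' @param q data.frame of measured quantities (Weight kg, Height cm, WC cm, HC cm).
#' @param variants see [index_variants()].
#' @return data.frame with one column per index; NA where inputs are missing
#'   or non-positive.
#' @export
compute_mass_ratios <- function(q, variants = index_variants()) {
  W <- guard_pos(col_or_na(q, "Weight"))
  H <- guard_pos(col_or_na(q, "Height"))
  WC <- guard_pos(col_or_na(q, "WC"))
  HC <- guard_pos(col_or_na(q, "HC"))
  Hm <- H / 100
  BMI <- W / Hm^2
  whtr <- if (variants$whtr_conventional) WC / H else (WC / 100) / Hm^2
  data.frame(
    BMI = BMI,
    PI = W / Hm^3,
    RPI = Hm / W^(1 / 3),
    BI = H - 100,
    WHR = WC / HC,
    WWI = WC / sqrt(W),
    WHT.5R = WC / sqrt(H),
    WHtR = whtr
  )
}

#' Population reference for the hip index
#'
#' The hip index scales hip circumference by cohort-average weight and
#' height; by default both references are computed from the records being
#' processed.
#'
#' @param records records data.frame, or NULL to supply constants.
#' @param mean_weight,mean_height optional explicit references (kg, cm).
#' @return list with `mean_weight` and `mean_height`, both strictly positive.
#' @export
population_reference <- function(records = NULL, mean_weight = NULL, mean_height = NULL) {
  if (is.null(mean_weight)) mean_weight <- mean(records$Weight, na.rm = TRUE)
  if (is.null(mean_height)) mean_height <- mean(records$Height, na.rm = TRUE)
  if (!is.finite(mean_weight) || mean_weight <= 0 ||
      !is.finite(mean_height) || mean_height <= 0) {
    stop("population reference weight and height must be strictly positive")
  }
  list(mean_weight = mean_weight, mean_height = mean_height)
}

#' Body-shape indices: ABSI, AVI, BAI, BRI, CI, HI, RFM
#'
#' ABSI = WC(m)/(BMI^(2/3) * H(m)^(1/2)); AVI = (2*WC^2 + 0.7*(WC-HC)^2)/1000
#' (cm); BAI = HC/H(m)^1.5 - 18; BRI = 364.2 - 365.5*sqrt(1 -
#' ((WC(m)/2pi)^2)/((0.5*H(m))^2)), unavailable when the radicand is negative
#' (WC > pi*H); conicity index CI = WC(m)/(0.109*sqrt(W/H(m))); hip index
#' HI = HC * (W/Wbar)^(-0.482) * (H/Hbar)^(0.310). Relative fat mass defaults
#' to the same-unit form RFM = 76 - 20*(H/WC) (female) / 64 - 20*(H/WC)
#' (male); `variants$rfm_as_printed` switches to the mixed-unit H(m)/WC(cm)
#' form found in some survey tabulations.
#'
#' @param q measured quantities data.frame.
#' @param d demographics data.frame with a `sex` column ("male"/"female");
#'   may be the same object as `q`.
#' @param ref population reference, see [population_reference()].
#' @param variants see [index_variants()].
#' @return data.frame of shape indices.
#' @export
compute_shape_indices <- function(q, d = q, ref = population_reference(q),
                                  variants = index_variants()) {
  W <- guard_pos(col_or_na(q, "Weight"))
  H <- guard_pos(col_or_na(q, "Height"))
  WC <- guard_pos(col_or_na(q, "WC"))
  HC <- guard_pos(col_or_na(q, "HC"))
  sex <- col_or_na(as.data.frame(d), "sex", n = length(W))
  Hm <- H / 100
  WCm <- WC / 100
  BMI <- W / Hm^2
  rad <- 1 - (WCm / (2 * pi))^2 / (0.5 * Hm)^2
  female <- sex == "female"
  rfm_ratio <- if (variants$rfm_as_printed) Hm / WC else H / WC
  data.frame(
    ABSI = WCm / (BMI^(2 / 3) * sqrt(Hm)),
    AVI = (2 * WC^2 + 0.7 * (WC - HC)^2) / 1000,
    BAI = HC / Hm^1.5 - 18,
    BRI = ifelse(!is.na(rad) & rad >= 0, 364.2 - 365.5 * sqrt(rad), NA_real_),
    CI = WCm / (0.109 * sqrt(W / Hm)),
    HI = HC * (W / ref$mean_weight)^(-0.482) * (H / ref$mean_height)^(0.310),
    RFM = ifelse(female, 76, 64) - 20 * rfm_ratio
  )
}

#' Body-composition indices: BF%, FFM, FFMI, LBM
#'
#' Deurenberg body fat percentage BF% = 1.20*BMI + 0.23*age - 16.2 (male) or
#' - 5.4 (female); fat free mass FFM = W*(1 - BF%/100); FFMI = FFM/H(m)^2;
#' Hume lean body mass, female 0.29569*W + 0.41813*H(cm) - 43.2933, male
#' 0.32810*W + 0.33929*H(cm) - 29.5336. BF% outside [0, 100] is retained
#' (flagged downstream by range checks), not dropped.
#'
#' @inheritParams compute_shape_indices
#' @return data.frame with columns BFP, FFM, FFMI, LBM.
#' @export
compute_composition <- function(q, d = q) {
  W <- guard_pos(col_or_na(q, "Weight"))
  H <- guard_pos(col_or_na(q, "Height"))
  dd <- as.data.frame(d)
  age <- col_or_na(dd, "age", n = length(W))
  sex <- col_or_na(dd, "sex", n = length(W))
  Hm <- H / 100
  BMI <- W / Hm^2
  male <- sex == "male"
  BFP <- 1.20 * BMI + 0.23 * age - ifelse(male, 16.2, 5.4)
  FFM <- W * (1 - BFP / 100)
  LBM <- ifelse(male,
                0.32810 * W + 0.33929 * H - 29.5336,
                0.29569 * W + 0.41813 * H - 43.2933)
  data.frame(BFP = BFP, FFM = FFM, FFMI = FFM / Hm^2, LBM = LBM)
}

#' Lipid-panel indices: AC, AIP, CRI-I, CRI-II, estimated LDL, THR, VLDL
#'
#' All inputs in mg/dl. AC = (TC-HDL)/HDL; AIP = log10(TG/HDL);
#' CRI-I = TC/HDL; estimated LDL defaults to TC - (HDL + 0.38*TG) with a
#' `variants$friedewald_ldl` flag for the Friedewald TC - HDL - TG/5;
#' CRI-II = LDL/HDL using measured LDL when present, estimated otherwise;
#' THR = TG/HDL; VLDL = TG/5. Ratio indices are unavailable when HDL is 0;
#' a negative estimated LDL is retained.
#'
#' @inheritParams compute_mass_ratios
#' @return data.frame with columns AC, AIP, CRI.I, CRI.II, LDL.est, THR, VLDL.
#' @export
compute_lipid_indices <- function(q, variants = index_variants()) {
  TC <- col_or_na(q, "TC")
  HDL <- guard_pos(col_or_na(q, "HDL"))
  TG <- col_or_na(q, "TG")
  LDLm <- col_or_na(q, "LDL")
  LDL.est <- if (variants$friedewald_ldl) TC - HDL - TG / 5 else TC - (HDL + 0.38 * TG)
  LDL_use <- ifelse(is.na(LDLm), LDL.est, LDLm)
  data.frame(
    AC = (TC - HDL) / HDL,
    AIP = log10(TG / HDL),
    CRI.I = TC / HDL,
    CRI.II = LDL_use / HDL,
    LDL.est = LDL.est,
    THR = TG / HDL,
    VLDL = TG / 5
  )
}

#' Glycaemic composites: TyG, LAP, VAI
#'
#' TyG = ln(TG(mg/dl) * FPG(mg/dl) / 2) (natural log; cohort means sit around
#' 8.2-8.8). Lipid accumulation product LAP = (WC - 58)*TG(mmol/l) for
#' females and (WC - 65)*TG for males; TG is converted from mg/dl internally
#' and a negative LAP (WC below the sex offset) is retained. Visceral
#' adiposity index, with TG and HDL in mmol/l:
#' female (WC/(36.58 + 1.89*BMI)) * (TG/0.81) * (1.52/HDL),
#' male (WC/(39.68 + 1.88*BMI)) * (TG/1.03) * (1.31/HDL).
#'
#' @inheritParams compute_shape_indices
#' @return data.frame with columns TyG, LAP, VAI.
#' @export
compute_glycaemic_indices <- function(q, d = q) {
  W <- guard_pos(col_or_na(q, "Weight"))
  H <- guard_pos(col_or_na(q, "Height"))
  WC <- guard_pos(col_or_na(q, "WC"))
  TG <- col_or_na(q, "TG")
  FPG <- col_or_na(q, "FPG")
  HDL <- guard_pos(col_or_na(q, "HDL"))
  sex <- col_or_na(as.data.frame(d), "sex", n = length(TG))
  BMI <- W / (H / 100)^2
  TGm <- convert_concentration(TG, "triglycerides", "mg/dl", "mmol/l")
  HDLm <- convert_concentration(HDL, "cholesterol", "mg/dl", "mmol/l")
  female <- sex == "female"
  VAI <- ifelse(female,
                (WC / (36.58 + 1.89 * BMI)) * (TGm / 0.81) * (1.52 / HDLm),
                (WC / (39.68 + 1.88 * BMI)) * (TGm / 1.03) * (1.31 / HDLm))
  data.frame(
    TyG = log(TG * FPG / 2),
    LAP = (WC - ifelse(female, 58, 65)) * TGm,
    VAI = VAI
  )
}

#' Derive every registry index for a batch of records
#'
#' Applies the full formula catalogue to a records data.frame and returns one
#' column per derived registry entry (plus BMI, which downstream formulas and
#' the core inventory both use). Unavailability propagates through the
#' dependency graph: an index is non-missing exactly when all of its required
#' inputs are, and no value is silently zero-filled.
#'
#' @param records data.frame with measured-quantity and demographic columns.
#' @param registry registry data.frame; defaults to [default_registry()].
#' @param ref population reference for the hip index; computed from
#'   `records` when NULL.
#' @param variants formula variant flags, see [index_variants()].
#' @return data.frame with `nrow(records)` rows and one column per derived
#'   index (BMI included).
#' @export
derive_all <- function(records, registry = default_registry(), ref = NULL,
                       variants = index_variants()) {
  validate_registry(registry, check_counts = FALSE)
  if (is.null(ref)) {
    ref <- if (all(is.na(records$Weight)) || all(is.na(records$Height))) {
      list(mean_weight = 1, mean_height = 1)  # HI inputs all NA anyway
    } else population_reference(records)
  }
  out <- cbind(
    compute_mass_ratios(records, variants),
    compute_shape_indices(records, d = records, ref = ref, variants = variants),
    compute_composition(records, d = records),
    compute_lipid_indices(records, variants),
    compute_glycaemic_indices(records, d = records)
  )
  derived <- registry$name[registry$category != "core"]
  keep <- c(intersect("BMI", registry$name), derived)
  missing_cols <- setdiff(keep, names(out))
  if (length(missing_cols)) stop("no formula for registry entries: ",
                                 paste(missing_cols, collapse = ", "))
  out[, keep, drop = FALSE]
}

#' Assemble the full 54-column predictor matrix
#'
#' Core measured metrics passed through (BMI computed from weight and
#' height), derived indices appended, columns ordered as in the registry.
#'
#' @inheritParams derive_all
#' @return data.frame with one column per registry metric.
#' @export
predictor_matrix <- function(records, registry = default_registry(), ref = NULL,
                             variants = index_variants()) {
  derived <- derive_all(records, registry, ref = ref, variants = variants)
  core <- registry$name[registry$category == "core"]
  out <- as.data.frame(matrix(NA_real_, nrow(records), nrow(registry),
                              dimnames = list(NULL, registry$name)))
  for (nm in core) {
    out[[nm]] <- if (nm == "BMI") derived$BMI
    else if (!is.null(records[[nm]])) as.numeric(records[[nm]])
    else rep(NA_real_, nrow(records))
  }
  for (nm in setdiff(registry$name, core)) out[[nm]] <- derived[[nm]]
  out
}
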