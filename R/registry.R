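#' @useDynLib diabscreen, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats median plogis quantile rbinom rnorm runif sd setNames uniroot var
#' @importFrom utils read.csv write.csv
NULL

#' Field inventories
#'
#' The measured-quantity and demographic field names shared by the registry,
#' the cohort generator and the preprocessing pipeline. Names are syntactic
#' versions of the canonical survey abbreviations (BF% -> BFP,
#' CRI-I -> CRI.I, A1C-DBS -> A1C.DBS).
#'
#' @return character vector of field names.
#' @export
measured_fields <- function() {
  c("Weight", "Height", "WC", "HC", "BPs", "BPd", "HRate", "PRate",
    "GripS_L", "GripS_R", "ArmC", "UAL", "KH",
    "FPG", "TC", "HDL", "LDL", "TG", "Hb", "HbA1c", "A1C.DBS", "CRP",
    "Potassium", "UC", "US")
}

#' @rdname measured_fields
#' @export
demographic_fields <- function() c("age", "sex", "race", "caste")

#' The default predictor-metric registry
#'
#' The catalogue of 54 predictor metrics used throughout the pipeline:
#' 26 core (measured) metrics and 28 derived anthropometric/biomarker
#' indices. BMI is classified as core: although computable from weight and
#' height it is inventoried alongside the measured metrics in survey
#' extracts, and the 26 + 28 = 54 split only balances under that convention.
#' The exact composition of the core list is a documented reconstruction of
#' the usual SAGE/STEPS/LASI/IFLS instrument inventory (it includes separate
#' heart-rate and pulse-rate channels and a dried-blood-spot HbA1c).
#'
#' Each entry records the metric name, a human-readable label, the category
#' (`core`, `derived-anthropometric`, `derived-biomarker`), the input fields
#' required to compute it, and whether the formula branches on sex.
#'
#' @return a data.frame with columns `name`, `label`, `category`, `inputs`
#'   (comma-separated field names), `sex_specific`.
#' @seealso [derive_all()], [write_registry()]
#' @export
default_registry <- function() {
  core <- c(Weight = "weight", Height = "height", WC = "waist circumference",
            HC = "hip circumference", BMI = "body mass index",
            BPs = "systolic blood pressure", BPd = "diastolic blood pressure",
            HRate = "heart rate", PRate = "pulse rate",
            GripS_L = "grip strength, left", GripS_R = "grip strength, right",
            ArmC = "arm circumference", UAL = "upper arm length",
            KH = "knee height", FPG = "fasting plasma glucose",
            TC = "total cholesterol", HDL = "HDL cholesterol",
            LDL = "LDL cholesterol (measured)", TG = "triglycerides",
            Hb = "haemoglobin", HbA1c = "glycated haemoglobin",
            A1C.DBS = "glycated haemoglobin (dried blood spot)",
            CRP = "C-reactive protein", Potassium = "potassium",
            UC = "urinary creatinine", US = "urinary sodium")

  d <- function(name, label, category, inputs, sex_specific = FALSE) {
    data.frame(name = name, label = label, category = category,
               inputs = paste(inputs, collapse = ","),
               sex_specific = sex_specific, stringsAsFactors = FALSE)
  }
  derived <- rbind(
    d("PI",      "ponderal (Rohrer's) index",        "derived-anthropometric", c("Weight", "Height")),
    d("RPI",     "reciprocal ponderal index",        "derived-anthropometric", c("Weight", "Height")),
    d("BI",      "Broca index",                      "derived-anthropometric", "Height"),
    d("WHR",     "waist-to-hip ratio",               "derived-anthropometric", c("WC", "HC")),
    d("WWI",     "weight-adjusted waist index",      "derived-anthropometric", c("WC", "Weight")),
    d("WHT.5R",  "waist-to-height^0.5 ratio",        "derived-anthropometric", c("WC", "Height")),
    d("WHtR",    "waist-to-height ratio",            "derived-anthropometric", c("WC", "Height")),
    d("ABSI",    "a body shape index",               "derived-anthropometric", c("WC", "Weight", "Height")),
    d("AVI",     "abdominal volume index",           "derived-anthropometric", c("WC", "HC")),
    d("BAI",     "body adiposity index",             "derived-anthropometric", c("HC", "Height")),
    d("BRI",     "body roundness index",             "derived-anthropometric", c("WC", "Height")),
    d("CI",      "conicity index",                   "derived-anthropometric", c("WC", "Weight", "Height")),
    d("HI",      "hip index",                        "derived-anthropometric", c("HC", "Weight", "Height")),
    d("RFM",     "relative fat mass",                "derived-anthropometric", c("WC", "Height"), TRUE),
    d("BFP",     "body fat percentage",              "derived-anthropometric", c("Weight", "Height", "age"), TRUE),
    d("FFM",     "fat free mass",                    "derived-anthropometric", c("Weight", "Height", "age"), TRUE),
    d("FFMI",    "fat free mass index",              "derived-anthropometric", c("Weight", "Height", "age"), TRUE),
    d("LBM",     "lean body mass",                   "derived-anthropometric", c("Weight", "Height"), TRUE),
    d("AC",      "atherogenic coefficient",          "derived-biomarker", c("TC", "HDL")),
    d("AIP",     "atherogenic index of plasma",      "derived-biomarker", c("TG", "HDL")),
    d("CRI.I",   "Castelli risk index I",            "derived-biomarker", c("TC", "HDL")),
    d("CRI.II",  "Castelli risk index II",           "derived-biomarker", c("TC", "HDL", "TG")),
    d("LDL.est", "estimated LDL cholesterol",        "derived-biomarker", c("TC", "HDL", "TG")),
    d("THR",     "triglyceride-to-HDL ratio",        "derived-biomarker", c("TG", "HDL")),
    d("VLDL",    "very low-density lipoprotein",     "derived-biomarker", "TG"),
    d("TyG",     "triglyceride-glucose index",       "derived-biomarker", c("TG", "FPG")),
    d("LAP",     "lipid accumulation product",       "derived-biomarker", c("WC", "TG"), TRUE),
    d("VAI",     "visceral adiposity index",         "derived-biomarker", c("WC", "Weight", "Height", "TG", "HDL"), TRUE)
  )
  core_df <- data.frame(name = names(core), label = unname(core),
                        category = "core", sex_specific = FALSE,
                        stringsAsFactors = FALSE)
  core_df$inputs <- ifelse(core_df$name == "BMI", "Weight,Height", core_df$name)
  registry <- rbind(core_df[, c("name", "label", "category", "inputs", "sex_specific")],
                    derived)
  rownames(registry) <- NULL
  validate_registry(registry)
  registry
}

#' Validate a predictor-metric registry
#'
#' Checks the structural invariants the pipeline relies on: unique names,
#' known categories, every declared input resolvable to a measured or
#' demographic field (or BMI, which other indices consume), and the default
#' 26 core / 28 derived inventory when `check_counts` is set.
#'
#' @param registry a registry data.frame (see [default_registry()]).
#' @param check_counts enforce the 26 + 28 default inventory.
#' @return the registry, invisibly; errors on violation.
#' @export
validate_registry <- function(registry, check_counts = TRUE) {
  stopifnot(is.data.frame(registry),
            all(c("name", "category", "inputs", "sex_specific") %in% names(registry)))
  if (anyDuplicated(registry$name)) {
    stop("registry names must be unique: ",
         paste(unique(registry$name[duplicated(registry$name)]), collapse = ", "))
  }
  ok_cat <- c("core", "derived-anthropometric", "derived-biomarker")
  if (!all(registry$category %in% ok_cat)) stop("unknown registry category")
  known <- c(measured_fields(), demographic_fields(), "BMI")
  ins <- unique(unlist(strsplit(registry$inputs, ",", fixed = TRUE)))
  bad <- setdiff(ins, known)
  if (length(bad)) stop("registry inputs reference unknown fields: ",
                        paste(bad, collapse = ", "))
  if (check_counts) {
    n_core <- sum(registry$category == "core")
    n_derived <- sum(registry$category != "core")
    if (n_core != 26L || n_derived != 28L) {
      stop("default registry must contain 26 core and 28 derived metrics, got ",
           n_core, " + ", n_derived)
    }
  }
  invisible(registry)
}

#' Write / read a registry as a structured YAML config
#'
#' @param registry a registry data.frame.
#' @param path file path.
#' @return `write_registry` returns `path` invisibly; `read_registry` returns
#'   a validated registry data.frame.
#' @export
write_registry <- function(registry, path) {
  validate_registry(registry, check_counts = FALSE)
  entries <- lapply(seq_len(nrow(registry)), function(i) {
    list(name = registry$name[i], label = registry$label[i],
         category = registry$category[i],
         inputs = strsplit(registry$inputs[i], ",", fixed = TRUE)[[1]],
         sex_specific = registry$sex_specific[i])
  })
  yaml::write_yaml(list(metrics = entries), path)
  invisible(path)
}

#' @rdname write_registry
#' @export
read_registry <- function(path) {
  obj <- yaml::read_yaml(path)
  registry <- do.call(rbind, lapply(obj$metrics, function(e) {
    data.frame(name = e$name, label = e$label, category = e$category,
               inputs = paste(unlist(e$inputs), collapse = ","),
               sex_specific = isTRUE(e$sex_specific), stringsAsFactors = FALSE)
  }))
  validate_registry(registry, check_counts = FALSE)
  registry
}
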