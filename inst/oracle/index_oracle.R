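# Independent scalar oracle for every derived-index formula: direct
# arithmetic on one respondent at a time, sharing no code with the package
# implementation. Used by the test suite and the acceptance script.

oracle_index <- function(name, W = NA, H = NA, WC = NA, HC = NA, age = NA,
                         sex = NA, TC = NA, HDL = NA, TG = NA, FPG = NA,
                         LDL = NA, Wbar = NA, Hbar = NA) {
  female <- identical(sex, "female")
  switch(name,
    BMI = W / (H / 100)^2,
    PI = W / (H / 100)^3,
    RPI = (H / 100) / W^(1 / 3),
    BI = H - 100,
    WHR = WC / HC,
    WWI = WC / sqrt(W),
    WHT.5R = WC / sqrt(H),
    WHtR = (WC / 100) / (H / 100)^2,
    ABSI = (WC / 100) / ((W / (H / 100)^2)^(2 / 3) * (H / 100)^(1 / 2)),
    AVI = (2 * WC * WC + 0.7 * (WC - HC) * (WC - HC)) / 1000,
    BAI = HC / (H / 100)^1.5 - 18,
    BRI = 364.2 - 365.5 * sqrt(1 - ((WC / 100) / (2 * pi))^2 / (0.5 * H / 100)^2),
    CI = (WC / 100) / (0.109 * sqrt(W / (H / 100))),
    HI = HC * (W / Wbar)^(-0.482) * (H / Hbar)^(0.310),
    RFM = (if (female) 76 else 64) - 20 * H / WC,
    BFP = 1.2 * (W / (H / 100)^2) + 0.23 * age - (if (female) 5.4 else 16.2),
    FFM = W * (1 - (1.2 * (W / (H / 100)^2) + 0.23 * age -
                      (if (female) 5.4 else 16.2)) / 100),
    FFMI = (W * (1 - (1.2 * (W / (H / 100)^2) + 0.23 * age -
                        (if (female) 5.4 else 16.2)) / 100)) / (H / 100)^2,
    LBM = if (female) 0.29569 * W + 0.41813 * H - 43.2933
          else 0.32810 * W + 0.33929 * H - 29.5336,
    AC = (TC - HDL) / HDL,
    AIP = log10(TG / HDL),
    CRI.I = TC / HDL,
    CRI.II = (if (is.na(LDL)) TC - (HDL + 0.38 * TG) else LDL) / HDL,
    LDL.est = TC - (HDL + 0.38 * TG),
    THR = TG / HDL,
    VLDL = TG / 5,
    TyG = log(TG * FPG / 2),
    LAP = (WC - (if (female) 58 else 65)) * (TG / 88.57),
    VAI = if (female) {
      (WC / (36.58 + 1.89 * W / (H / 100)^2)) * ((TG / 88.57) / 0.81) *
        (1.52 / (HDL / 38.67))
    } else {
      (WC / (39.68 + 1.88 * W / (H / 100)^2)) * ((TG / 88.57) / 1.03) *
        (1.31 / (HDL / 38.67))
    },
    stop("no oracle for ", name)
  )
}

# random physiologically valid single-record inputs for the oracle suite
random_oracle_input <- function() {
  list(W = runif(1, 40, 140), H = runif(1, 140, 200),
       WC = runif(1, 55, 140), HC = runif(1, 70, 150),
       age = runif(1, 18, 90), sex = sample(c("male", "female"), 1),
       TC = runif(1, 80, 300), HDL = runif(1, 15, 90),
       TG = runif(1, 40, 400), FPG = runif(1, 60, 250),
       LDL = runif(1, 50, 220),
       Wbar = runif(1, 55, 85), Hbar = runif(1, 150, 175))
}
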