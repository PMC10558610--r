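# The independent formula oracle lives with the installed package (it is
# shared with scripts/acceptance.R); it is direct scalar arithmetic with no
# code in common with the implementation under test.
source(system.file("oracle", "index_oracle.R", package = "diabscreen"),
       local = environment())

derived_index_names <- function() {
  reg <- default_registry()
  reg$name[reg$category != "core"]
}

# package-side evaluation of one index for a single respondent
package_index_value <- function(name, inp) {
  rec <- data.frame(Weight = inp$W, Height = inp$H, WC = inp$WC, HC = inp$HC,
                    age = inp$age, sex = inp$sex, TC = inp$TC, HDL = inp$HDL,
                    TG = inp$TG, FPG = inp$FPG, LDL = inp$LDL)
  ref <- population_reference(mean_weight = inp$Wbar, mean_height = inp$Hbar)
  derive_all(rec, ref = ref)[[name]]
}
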