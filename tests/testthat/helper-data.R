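# Small builders for long-format trial fixtures.

rec <- function(treatment, trait, values, region = "R1") {
  data.frame(region = region, treatment = treatment,
             replicate = seq_along(values), trait = trait, value = values,
             stringsAsFactors = FALSE)
}

two_group_trial <- function(control_values, treatment_values,
                            trait = "yield", region = "R1") {
  rbind(rec("control", trait, control_values, region),
        rec("trt", trait, treatment_values, region))
}
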