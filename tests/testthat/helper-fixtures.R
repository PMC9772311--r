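# Shared fixtures: gas constants and the cohort-mean conditions used across
# the suite.

bd_gas <- gas_spec("BD", molar_mass = 54.09)
st_gas <- gas_spec("ST", molar_mass = 104.15)

bd_preset <- analyte_preset("BD")
st_preset <- analyte_preset("ST")

mean_factors_bd <- cohort_mean_factors(C = 0.039)
mean_factors_st <- cohort_mean_factors(C = 12.108)

# all-point distribution set at the cohort means (degenerate Monte Carlo)
point_specs <- function(C = 0.039) {
  list(
    C = dist_spec("C", "point", value = C),
    EF = dist_spec("EF", "point", value = 301.06),
    ED = dist_spec("ED", "point", value = 29.66),
    BW = dist_spec("BW", "point", value = 74.45),
    ET = dist_spec("ET", "point", value = 10.81)
  )
}
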