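{
  "required": ["states", "transitions", "death", "utilities", "costs",
               "treatment_effect", "discounting", "simulation"],
  "transitions_fields": ["from", "to", "sex", "p"],
  "death_fields": ["state", "sex", "p"],
  "utilities_keys": ["asymptomatic", "acro_or_symptoms",
                     "single_complication", "multiple_complications"],
  "costs_required": ["state", "ert_per_year", "unit_cost_hour"],
  "treatment_effect_required": ["or_first", "or_second",
                                "median_duration_symptoms",
                                "median_duration_single_complication"],
  "discounting_required": ["effects", "costs"],
  "simulation_required": ["horizon", "cycle_length", "sex_mix",
                          "ert_start_rule"]
}
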