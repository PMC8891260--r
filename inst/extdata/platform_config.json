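{
  "comment": "Platform calibration and cost constants. Batch cycle times, CapEx references and material recipes are the lumped model's calibration knobs: they were tuned once so that baseline and design-median outputs reproduce published techno-economic anchors for the three platforms, then frozen. All monetary values in nominal USD.",
  "capex_exponent": 0.6,
  "capex_annualisation": 0.14,
  "labour_hours_per_year": 8760,
  "platforms": {
    "avv": {
      "batch_cycle_days": 14.5,
      "operating_days": 330,
      "parallel_lines": 1,
      "reference_scale_l": 2000,
      "reference_capex_usd": 1.7e8,
      "crew_per_line": 60,
      "materials": {
        "basis": "per_litre_batch",
        "cost_usd_per_l_batch": 690,
        "comment": "cell-culture media, transfection/infection reagents, chromatography consumables, buffers; lumped per litre of bioreactor working volume per batch started"
      }
    },
    "mrna": {
      "batch_cycle_days": 0.75,
      "operating_days": 330,
      "parallel_lines": 1,
      "reference_scale_l": 30,
      "reference_capex_usd": 1.05e8,
      "crew_per_line": 15,
      "materials": {
        "basis": "per_gram_rna",
        "cap_analogue_g_per_g": 0.3,
        "other_usd_per_g": 10300,
        "comment": "5' cap analogue usage from co-transcriptional capping stoichiometry; 'other' lumps nucleotides, plasmid template, T7 polymerase, the four LNP lipids and single-use consumables per gram of RNA"
      }
    },
    "sarna": {
      "batch_cycle_days": 0.65,
      "operating_days": 330,
      "parallel_lines": 1,
      "reference_scale_l": 5,
      "reference_capex_usd": 2.8e7,
      "crew_per_line": 10,
      "materials": {
        "basis": "per_gram_rna",
        "cap_analogue_g_per_g": 0.3,
        "other_usd_per_g": 10300,
        "comment": "shared with mRNA: identical cell-free reaction and LNP chemistry"
      }
    }
  },
  "fill_finish": {
    "vial5":  {"technology": "multi-dose vial",          "doses_per_container": 5,   "containers_per_minute": 400, "oee": 0.6, "operating_minutes": 525600, "cost_per_container_usd": 1.5, "capex_usd": 1.5e8, "opex_fixed_usd_per_year": 2.8e7},
    "vial10": {"technology": "multi-dose vial",          "doses_per_container": 10,  "containers_per_minute": 400, "oee": 0.6, "operating_minutes": 525600, "cost_per_container_usd": 1.5, "capex_usd": 1.5e8, "opex_fixed_usd_per_year": 2.8e7},
    "bfs1":   {"technology": "blow-fill-seal single-dose","doses_per_container": 1,  "containers_per_minute": 400, "oee": 0.6, "operating_minutes": 525600, "cost_per_container_usd": 0.4, "capex_usd": 1.5e8, "opex_fixed_usd_per_year": 2.8e7},
    "bag200": {"technology": "200-dose bag",             "doses_per_container": 200, "containers_per_minute": 10,  "oee": 0.6, "operating_minutes": 525600, "cost_per_container_usd": 30,  "capex_usd": 1.5e8, "opex_fixed_usd_per_year": 2.8e7}
  },
  "demand": {
    "targets_doses_per_year": [1e9, 2.4e9, 11.3e9],
    "global_gap_doses": 11.3e9,
    "vulnerable_population": 2.2e9,
    "frontline_personnel": 2e8
  }
}
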