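{
  "comment": "Uncertain input factors per vaccine production platform. dist is 'triangular' (mode = most probable central value) or 'uniform' (mode null). Units: scale in litres of bioreactor working volume; titre in g RNA per litre for the RNA platforms and viral particles per litre for AVV; dose in micrograms RNA per dose (RNA) or viral particles per dose (AVV); failure and qc_share in percent; cap analogue price in USD per gram; labour rate in USD per hour.",
  "avv": [
    {"name": "scale",     "units": "L",            "dist": "triangular", "low": 1000,     "mode": 2000,    "high": 20000},
    {"name": "failure",   "units": "%",            "dist": "uniform",    "low": 0,        "mode": null,    "high": 15},
    {"name": "titre",     "units": "vp L-1",       "dist": "triangular", "low": 1e14,     "mode": 2.5e14,  "high": 7e14},
    {"name": "labour",    "units": "USD h-1",      "dist": "triangular", "low": 5,        "mode": 23,      "high": 30},
    {"name": "dose",      "units": "vp dose-1",    "dist": "triangular", "low": 2.2e10,   "mode": 5e10,    "high": 6.5e10},
    {"name": "qc_share",  "units": "% of labour",  "dist": "uniform",    "low": 30,       "mode": null,    "high": 80}
  ],
  "mrna": [
    {"name": "scale",     "units": "L",            "dist": "triangular", "low": 2,        "mode": 30,      "high": 200},
    {"name": "failure",   "units": "%",            "dist": "uniform",    "low": 0,        "mode": null,    "high": 10},
    {"name": "titre",     "units": "g L-1",        "dist": "triangular", "low": 3,        "mode": 5,       "high": 7},
    {"name": "cap_price", "units": "USD g-1",      "dist": "triangular", "low": 2500,     "mode": 3000,    "high": 10000},
    {"name": "labour",    "units": "USD h-1",      "dist": "triangular", "low": 5,        "mode": 23,      "high": 30},
    {"name": "dose",      "units": "ug dose-1",    "dist": "triangular", "low": 5,        "mode": 30,      "high": 150},
    {"name": "qc_share",  "units": "% of labour",  "dist": "uniform",    "low": 30,       "mode": null,    "high": 80}
  ],
  "sarna": [
    {"name": "scale",     "units": "L",            "dist": "triangular", "low": 0.5,      "mode": 5,       "high": 50},
    {"name": "failure",   "units": "%",            "dist": "uniform",    "low": 0,        "mode": null,    "high": 10},
    {"name": "titre",     "units": "g L-1",        "dist": "triangular", "low": 3,        "mode": 5,       "high": 7},
    {"name": "cap_price", "units": "USD g-1",      "dist": "triangular", "low": 2500,     "mode": 3000,    "high": 10000},
    {"name": "labour",    "units": "USD h-1",      "dist": "triangular", "low": 5,        "mode": 23,      "high": 30},
    {"name": "dose",      "units": "ug dose-1",    "dist": "triangular", "low": 0.1,      "mode": 1,       "high": 10},
    {"name": "qc_share",  "units": "% of labour",  "dist": "uniform",    "low": 30,       "mode": null,    "high": 80}
  ]
}
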