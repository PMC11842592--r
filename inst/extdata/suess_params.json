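{
  "comment": "Regional Suess/Laws drift curve constants. RECONSTRUCTED from published regional annual d13C decline rates (~0.02 per mil/yr in the modern North Atlantic), not extracted from any package source. a: decline rate at 1850 (per mil/yr); r_growth: exponential growth of the rate (1/yr); sst_trend: regional SST trend (deg C/yr); laws_sens: Laws-effect sensitivity (per mil per deg C).",
  "regions": {
    "north_atlantic": {
      "a": 3.83e-4,
      "r_growth": 0.027,
      "sst_trend": 0.005,
      "laws_sens": -0.3
    },
    "subpolar_north_atlantic": {
      "a": 3.3e-4,
      "r_growth": 0.027,
      "sst_trend": 0.004,
      "laws_sens": -0.3
    }
  }
}
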