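# Published occupational exposure limits for the analytes covered by the
# bundled preset. Values in ppm; TWA limits assume an 8 h / 40 h schedule.
limits:
  - {agency: OSHA,  analyte: BD, limit_type: TWA,  value_ppm: 1}
  - {agency: OSHA,  analyte: BD, limit_type: STEL, value_ppm: 5}
  - {agency: ACGIH, analyte: BD, limit_type: TWA,  value_ppm: 2}
  - {agency: EOHCI, analyte: BD, limit_type: TWA,  value_ppm: 2}
  - {agency: OSHA,  analyte: ST, limit_type: TWA,  value_ppm: 100}
  - {agency: ACGIH, analyte: ST, limit_type: TWA,  value_ppm: 20}
  - {agency: EOHCI, analyte: ST, limit_type: TWA,  value_ppm: 20}
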