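entries:
  rod:
  - NRL
  - RHO
  - GNGT1
  - CNGA1
  cone:
  - ARR3
  - PDE6H
  - GNAT2
  - OPN1SW
  HC:
  - ONECUT1
  - ONECUT2
  BC:
  - VSX2
  - TRPM1
  - GRM6
  MG:
  - RLBP1
  - GLUL
  - APOE
  - SLC1A3
  AC:
  - GAD1
  - SLC6A9
  - TFAP2A
  microglia:
  - AIF1
  - C1QA
  - CX3CR1
subtype_rules:
  HC:
    H1:
      positive:
      - LHX1
      - PCP4
      negative:
      - ISL1
      - CALB1
    H2:
      positive:
      - ISL1
      - CALB1
      negative:
      - LHX1
      - PCP4
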