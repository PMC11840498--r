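# Example audit protocol: clinically relevant OARs with their sDSC
# tolerances (mm) and the structure-name aliases seen in exported data.
audit_start: 2023-01-01
period_length_months: 2
default_tolerance_mm: 3
outlier_k: 2
min_n_for_outlier: 5
oars:
  Bladder:
    aliases: [Bladder_O, Urinary Bladder]
  Rectum: {}
  Femoral Head:
    aliases: [FemHead_L, FemHead_R, Fem Head]
  Spinal Cord:
    tolerance_mm: 2
    aliases: [SpinalCord, Cord]
  Oesophagus:
    aliases: [Esophagus]
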