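# Coastal cutthroat trout (Oncorhynchus clarkii)
# Approximate transcription after Beauchamp et al. (1995): Thornton-Lessem
# consumption with a warmer falling limb than Chinook (higher thermal
# tolerance), Stewart-form respiration. Qualitative use only.
species: cutthroat
consumption:
  form: thornton_lessem
  CA: 0.303
  CB: -0.275
  CQ: 5
  CTO: 15
  CTM: 22
  CTL: 26
  CK1: 0.36
  CK4: 0.1
respiration:
  form: swim_speed
  RA: 0.00264
  RB: -0.217
  RQ: 0.06818
  RTO: 0.0234
  RTM: 0
  RTL: 25
  RK1: 1
  RK4: 0.13
  ACT: 9.7
  BACT: 0.0405
waste:
  form: elliott
  FA: 0.212
  FB: -0.222
  FG: 0.631
  UA: 0.0314
  UB: 0.58
  UG: -0.299
sda: 0.172
oxycal: 13560
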