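# Juvenile sockeye salmon (Oncorhynchus nerka)
# Approximate transcription after Beauchamp, Stewart & Thomas (1989):
# Thornton-Lessem consumption with a cooler lower anchor than Chinook and
# the Stewart-form swim-speed respiration. Used only for qualitative
# species comparison; not anchored by a quantitative acceptance check.
species: sockeye
consumption:
  form: thornton_lessem
  CA: 0.303
  CB: -0.275
  CQ: 3
  CTO: 15
  CTM: 18
  CTL: 24.9
  CK1: 0.36
  CK4: 0.01
respiration:
  form: swim_speed
  RA: 0.00143
  RB: -0.209
  RQ: 0.086
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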