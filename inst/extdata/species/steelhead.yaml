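# Juvenile steelhead / rainbow trout (Oncorhynchus mykiss)
# Approximate transcription after Rand, Stewart et al. (1993): Kitchell
# dome consumption with optimum 20 degC and lethal limit 25 degC (the
# higher thermal tolerance relative to Chinook that the species comparison
# relies on), Stewart-form respiration. Qualitative use only.
species: steelhead
consumption:
  form: dome
  CA: 0.628
  CB: -0.3
  CQ: 5          # Q10-like slope parameter of the dome
  CTO: 20        # optimum, degC
  CTM: 25        # lethal, degC
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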