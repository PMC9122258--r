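# Juvenile Chinook salmon (Oncorhynchus tshawytscha)
# Consumption: Thornton-Lessem double sigmoid with the re-estimated
#   juvenile temperature parameters of Plumb & Moffitt (2015); allometry
#   (CA, CB) from Stewart & Ibarra (1991). This is the Fish Bioenergetics
#   4.0 juvenile-Chinook default set.
# Respiration: swim-speed-dependent exponential of Stewart & Ibarra (1991).
# Egestion/excretion: Elliott-form coefficients of Stewart & Ibarra (1991).
species: chinook
consumption:
  form: thornton_lessem
  CA: 0.303      # g/g/d intercept at 1 g
  CB: -0.275     # mass exponent
  CQ: 1.25       # lower temperature anchor, degC
  CTO: 20.93     # upper inflection of the rising limb, degC
  CTM: 20.93     # start of the falling limb, degC
  CTL: 24.05     # upper temperature anchor, degC
  CK1: 0.36      # proportion of maximum at CQ
  CK4: 0.53      # proportion of maximum at CTL
respiration:
  form: swim_speed
  RA: 0.00264    # g O2/g/d intercept at 1 g, 0 degC, zero velocity
  RB: -0.217
  RQ: 0.06818    # per degC
  RTO: 0.0234    # per cm/s of swimming speed
  RTM: 0
  RTL: 25        # cutoff temperature for temperature-dependent velocity
  RK1: 1
  RK4: 0.13      # mass exponent of swimming speed
  ACT: 9.7       # velocity intercept, cm/s at 1 g, 0 degC
  BACT: 0.0405   # per degC
waste:
  form: elliott
  FA: 0.212
  FB: -0.222
  FG: 0.631
  UA: 0.0314
  UB: 0.58
  UG: -0.299
sda: 0.172
oxycal: 13560    # J per g O2
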