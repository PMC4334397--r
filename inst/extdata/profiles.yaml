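# Cohort profiles for the virtual-subject generator (synthetic; no clinical
# data). Circuit-element laws are log-normal: median (natural units) and
# sdlog. Units: resistances cmH2O/L/s, inertance cmH2O/L/s^2, compliance
# L/cmH2O, amplitudes cmH2O (pressure) and L/s (flow), frequencies Hz.
control:
  param_law:
    R:  {median: 1.8,   sdlog: 0.25}
    Rp: {median: 1.2,   sdlog: 0.30}
    I:  {median: 0.008, sdlog: 0.20}
    C:  {median: 0.020, sdlog: 0.25}
  excitation_amplitude: 1.0
  breathing_frequency: 0.2
  breathing_flow_amplitude: 0.3
  pressure_noise_sd: 0.02
  flow_noise_sd: 0.005
cf:
  param_law:
    # R law here is a pre-calibration placeholder: fot_profile("cf")
    # replaces it via calibrate_profile() against r0_target below.
    R:  {median: 1.1,   sdlog: 0.60}
    Rp: {median: 3.2,   sdlog: 0.30}
    I:  {median: 0.005, sdlog: 0.25}
    C:  {median: 0.006, sdlog: 0.35}
  excitation_amplitude: 1.0
  breathing_frequency: 0.2
  breathing_flow_amplitude: 0.3
  pressure_noise_sd: 0.02
  flow_noise_sd: 0.005
  r0_target: {mean: 4.71, sd: 1.52}
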