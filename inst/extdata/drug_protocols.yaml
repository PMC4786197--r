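SSA_DRUG:
  name: SSA_DRUG
  type: ssa
  sweep:
  - -130.0
  - -120.0
  - -110.0
  - -100.0
  - -90.0
  - -80.0
  - -70.0
  - -60.0
  - -50.0
  holding: -120.0
  cond_dur: 500.0
  test_v: -20.0
  test_dur: 25.0
TB:
  name: TB
  type: tb
  sweep:
  - 1.0e-05
  - 1.0e-04
  holding: -100.0
  test_v: -20.0
  test_dur: 25.0
UDB:
  name: UDB
  type: udb
  sweep:
  - 1.0e-05
  - 1.0e-04
  holding: -100.0
  pulse_v: -20.0
  pulse_dur: 25.0
  n_pulses: 30.0
  freq: 10.0
RUDB_DRUG:
  name: RUDB_DRUG
  type: rudb
  sweep:
  - 1.0
  - 3.0
  - 10.0
  - 30.0
  - 100.0
  - 300.0
  - 1000.0
  - 3000.0
  holding: -100.0
  pulse_v: -20.0
  pulse_dur: 25.0
  n_pulses: 30.0
  freq: 10.0
  test_v: -20.0
  test_dur: 25.0
  conc: 0.0001
FDUDB:
  name: FDUDB
  type: fdudb
  sweep:
  - 2.0
  - 5.0
  - 10.0
  - 20.0
  holding: -100.0
  pulse_v: -20.0
  pulse_dur: 25.0
  n_pulses: 30.0
  conc: 0.0001
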