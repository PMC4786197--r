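SSA:
  name: SSA
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
ACT:
  name: ACT
  type: act
  sweep:
  - -75.0
  - -65.0
  - -55.0
  - -45.0
  - -35.0
  - -25.0
  - -15.0
  - -5.0
  - 5.0
  - 15.0
  holding: -120.0
  test_dur: 25.0
RFI:
  name: RFI
  type: rfi
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
  p1_v: -20.0
  p1_dur: 100.0
  rec_v: -100.0
  p2_v: -20.0
  p2_dur: 25.0
RUDB:
  name: RUDB
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
  n_pulses: 50.0
  freq: 10.0
  test_v: -20.0
  test_dur: 25.0
TAU50:
  name: TAU50
  type: tau50
  sweep:
  - -40.0
  - -30.0
  - -20.0
  - -10.0
  - 0.0
  - 10.0
  holding: -120.0
  test_dur: 100.0
MOT:
  name: MOT
  type: mot
  sweep: -30.0
  holding: -100.0
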