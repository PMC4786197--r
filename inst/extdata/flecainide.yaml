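pKa: 9.3
pH: 7.4
diffusion: 5500.0
concentration: 1.0e-05
d: 0.7
T: 295.0
kd0_charged_open: 1.12e-05
kd_neutral_open: 0.0004
kd_neutral_closed: 0.0008
kd_neutral_inactivated: 5.4e-06
v_ref_closed: -100.0
charged:
  ax1: 1.0836e-05
  bx1: 4.2106e-08
  a13c: 0.0024824
  a22: 126.63
  b33: 4.881e-06
  a33: 0.0001831
  a44: 2.5183
  b44: 0.046378
neutral:
  ax2: 1.0
  a13n: 1.0
  a_22: 1.0
  b_33: 1.0
  a_44: 1.0
  b_44: 1.0
  ki_on: 5500.0
  ki_off: 0.0297
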