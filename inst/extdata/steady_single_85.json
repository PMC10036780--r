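{
  "V": -85.3950788023292,
  "m": 0.00165631566493949,
  "h": 0.749398696031576,
  "j": 0.748656803811612,
  "xr1": 0.000207699884731953,
  "xr2": 0.472891102648092,
  "xs": 0.00323448008913075,
  "r": 2.3511640469685e-08,
  "s": 0.999997910964365,
  "d": 3.2987872175364e-05,
  "f": 0.97585449416479,
  "f2": 0.999397600437596,
  "fcass": 0.999962964080228,
  "ryr_r": 0.984107908381937,
  "ryr_o": 2.21305107574273e-07,
  "ryr_i": 3.573886342725e-09,
  "ryr_ri": 0.0158918667390689,
  "Na_i": 10.7326756975186,
  "K_i": 134.730410591264,
  "Ca_i": 9.92015015997882e-05,
  "Ca_ss": 0.000231993299185317,
  "Ca_sr": 3.14796890559741,
  "CaTnC": 0.00239421292440623,
  "l1": 0.0426851945810682,
  "l2": 0.0449849212022164,
  "N_xb": 0.00298505952548001
}
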