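{
  "V": -85.3918386987008,
  "m": 0.00165745642934138,
  "h": 0.749306633051706,
  "j": 0.748443516707704,
  "xr1": 0.000207848167241178,
  "xr2": 0.472857305272844,
  "xs": 0.00323623294317992,
  "r": 2.35246320777047e-08,
  "s": 0.999997909537514,
  "d": 3.30021590118618e-05,
  "f": 0.975899619946689,
  "f2": 0.999397456720391,
  "fcass": 0.999962773341922,
  "ryr_r": 0.984093035123521,
  "ryr_o": 2.29617785988183e-07,
  "ryr_i": 3.71165324027178e-09,
  "ryr_ri": 0.01590673154704,
  "Na_i": 10.7336190591645,
  "K_i": 134.728534129379,
  "Ca_i": 9.94954930149858e-05,
  "Ca_ss": 0.000233731711096695,
  "Ca_sr": 3.15373349264838,
  "CaTnC": 0.00240984682298213,
  "l1": 0.0871322029566087,
  "l2": 0.0900311065925155,
  "N_xb": 0.00348585018041603
}
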