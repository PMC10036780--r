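{
  "V": -85.3979859065324,
  "m": 0.00165529280907256,
  "h": 0.749480845262065,
  "j": 0.748841430554342,
  "xr1": 0.0002075669638618,
  "xr2": 0.47292141209511,
  "xs": 0.00323315664032576,
  "r": 2.35000194790003e-08,
  "s": 0.999997912236428,
  "d": 3.29750622345297e-05,
  "f": 0.975757540418488,
  "f2": 0.999397166931606,
  "fcass": 0.999963122739605,
  "ryr_r": 0.984118922573402,
  "ryr_o": 2.13123756625584e-07,
  "ryr_i": 3.43934277232206e-09,
  "ryr_ri": 0.0158808608634983,
  "Na_i": 10.7310495310452,
  "K_i": 134.732840715422,
  "Ca_i": 9.89416285925257e-05,
  "Ca_ss": 0.00023015762825124,
  "Ca_sr": 3.14209009575302,
  "CaTnC": 0.00237951342460942,
  "l1": -0.00336360779432649,
  "l2": -0.00164785592987904,
  "N_xb": 0.00248361623786648
}
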