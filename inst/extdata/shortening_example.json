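{
  "geometry": {
    "nx": 1,
    "ny": 1,
    "nz": 1,
    "L": 2,
    "fiber_axis": 1
  },
  "material": {
    "c10": 6.352e-10,
    "c01": 3.627,
    "b1": 2.756e-05,
    "d1": 43.373,
    "Pmax": 73,
    "lambda_opt": 1.2,
    "a_rel": 0.25,
    "b_rel": 0.25,
    "vmax": 0.02,
    "Fiso": 1,
    "sigma": 3.8,
    "Am": 500,
    "Cm_slow": 0.58,
    "Cm_fast": 1
  },
  "fibers": {
    "n_fibers": 4,
    "n_elem_per_fiber": 16
  },
  "cellmodel": {
    "name": "reduced",
    "fiber_type": "fast",
    "params": []
  },
  "stimulus": {
    "frequency": 50,
    "amplitude": 700,
    "width": 0.5
  },
  "schedule": {
    "dt_hsm": 0.001,
    "n_hsm_per_deq": 10,
    "n_deq_per_cmm": 50,
    "t_end": 60
  },
  "experiment": {
    "mode": "shortening",
    "prestretch": 0.2,
    "t_prestretch": 10,
    "speed_fraction": 0.1,
    "lumped_mass": false
  },
  "output": {
    "dir": "",
    "write_csv": false,
    "write_vtu": false
  }
}
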