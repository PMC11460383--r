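{
  "H": {
    "a": [0.493002, 0.322912, 0.140191, 0.04081],
    "b": [10.5109, 26.1257, 3.14236, 57.7997],
    "c": 0.003038,
    "z": 1,
    "weight": 1.00794,
    "vdw_r": 1.20000004768372
  },
  "C": {
    "a": [2.31, 1.02, 1.5886, 0.865],
    "b": [20.8439, 10.2075, 0.5687, 51.6512],
    "c": 0.2156,
    "z": 6,
    "weight": 12.0107,
    "vdw_r": 1.70000004768372
  },
  "N": {
    "a": [12.2126, 3.1322, 2.0125, 1.1663],
    "b": [0.0057, 9.8933, 28.9975, 0.5826],
    "c": -11.529,
    "z": 7,
    "weight": 14.0067,
    "vdw_r": 1.54999995231628
  },
  "O": {
    "a": [3.0485, 2.2868, 1.5463, 0.867],
    "b": [13.2771, 5.7011, 0.3239, 32.9089],
    "c": 0.2508,
    "z": 8,
    "weight": 15.9994,
    "vdw_r": 1.51999998092651
  },
  "S": {
    "a": [6.9053, 5.2034, 1.4379, 1.5863],
    "b": [1.4679, 22.2151, 0.2536, 56.172],
    "c": 0.8669,
    "z": 16,
    "weight": 32.065,
    "vdw_r": 1.79999995231628
  },
  "P": {
    "a": [6.4345, 4.1791, 1.78, 1.4908],
    "b": [1.9067, 27.157, 0.526, 68.1645],
    "c": 1.1149,
    "z": 15,
    "weight": 30.973761,
    "vdw_r": 1.79999995231628
  },
  "Na": {
    "a": [4.7626, 3.1736, 1.2674, 1.1128],
    "b": [3.285, 8.8422, 0.3136, 129.424],
    "c": 0.676,
    "z": 11,
    "weight": 22.98977,
    "vdw_r": 2.26999998092651
  },
  "Mg": {
    "a": [5.4204, 2.1735, 1.2269, 2.3073],
    "b": [2.8275, 79.2611, 0.3808, 7.1937],
    "c": 0.8584,
    "z": 12,
    "weight": 24.305,
    "vdw_r": 1.73000001907349
  },
  "K": {
    "a": [8.2186, 7.4398, 1.0519, 0.8659],
    "b": [12.7949, 0.7748, 213.187, 41.6841],
    "c": 1.4228,
    "z": 19,
    "weight": 39.0983,
    "vdw_r": 2.75
  },
  "Ca": {
    "a": [8.6266, 7.3873, 1.5899, 1.0211],
    "b": [10.4421, 0.6599, 85.7484, 178.437],
    "c": 1.3751,
    "z": 20,
    "weight": 40.078,
    "vdw_r": 2.30999994277954
  },
  "Cl": {
    "a": [11.4604, 7.1964, 6.2556, 1.6455],
    "b": [0.0104, 1.1662, 18.5194, 47.7784],
    "c": -9.5574,
    "z": 17,
    "weight": 35.453,
    "vdw_r": 1.75
  },
  "Mn": {
    "a": [11.2819, 7.3573, 3.0193, 2.2441],
    "b": [5.3409, 0.3432, 17.8674, 83.7543],
    "c": 1.0896,
    "z": 25,
    "weight": 54.93805,
    "vdw_r": 1.19000005722046
  },
  "Fe": {
    "a": [11.7695, 7.3573, 3.5222, 2.3045],
    "b": [4.7611, 0.3072, 15.3535, 76.8805],
    "c": 1.0369,
    "z": 26,
    "weight": 55.845,
    "vdw_r": 1.25999999046326
  },
  "Zn": {
    "a": [14.0743, 7.0318, 5.1652, 2.41],
    "b": [3.2655, 0.2333, 10.3163, 58.7097],
    "c": 1.3041,
    "z": 30,
    "weight": 65.38,
    "vdw_r": 1.38999998569489
  },
  "Cu": {
    "a": [13.338, 7.1676, 5.6158, 1.6735],
    "b": [3.5828, 0.247, 11.3966, 64.8126],
    "c": 1.191,
    "z": 29,
    "weight": 63.546,
    "vdw_r": 1.39999997615814
  },
  "Se": {
    "a": [17.0006, 5.8196, 3.9731, 4.3543],
    "b": [2.4098, 0.2726, 15.2372, 43.8163],
    "c": 2.8409,
    "z": 34,
    "weight": 78.96,
    "vdw_r": 1.89999997615814
  },
  "I": {
    "a": [20.1472, 18.9949, 7.5138, 2.2735],
    "b": [4.347, 0.3814, 27.766, 66.8776],
    "c": 4.0712,
    "z": 53,
    "weight": 126.90447,
    "vdw_r": 1.98000001907349
  }
}
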