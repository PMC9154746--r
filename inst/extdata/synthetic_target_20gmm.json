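{
  "kind": "synthetic_gmm_target",
  "Ns": 200,
  "m": 20,
  "seed": 11,
  "sd_range": [1.5, 2.5],
  "min_frac": 0.2,
  "components": [
    {
      "weight": 0.0663261242322087,
      "mean": 8.67523731131639,
      "sd": 1.70371259469539
    },
    {
      "weight": 0.0719946190902185,
      "mean": 17.1448316682308,
      "sd": 2.18036738759838
    },
    {
      "weight": 0.0384703539359683,
      "mean": 28.6118414208648,
      "sd": 1.86378802801482
    },
    {
      "weight": 0.0271615521202559,
      "mean": 36.2439920318623,
      "sd": 1.85034838342108
    },
    {
      "weight": 0.0548350598682201,
      "mean": 45.9607229585804,
      "sd": 1.56198844383471
    },
    {
      "weight": 0.0159012326972787,
      "mean": 58.8756160970245,
      "sd": 1.98301775055006
    },
    {
      "weight": 0.0281396710742258,
      "mean": 65.0914129189083,
      "sd": 1.8991432855837
    },
    {
      "weight": 0.182806977409212,
      "mean": 75.3903809872766,
      "sd": 1.51621457794681
    },
    {
      "weight": 0.0356702260059406,
      "mean": 87.1645682775194,
      "sd": 1.62508325534873
    },
    {
      "weight": 0.0173037894240051,
      "mean": 93.802728385975,
      "sd": 1.89814944239333
    },
    {
      "weight": 0.0377270632107453,
      "mean": 103.524239705432,
      "sd": 2.00491762650199
    },
    {
      "weight": 0.0307539952663672,
      "mean": 114.060001035354,
      "sd": 1.82767935842276
    },
    {
      "weight": 0.0444552452834542,
      "mean": 125.360697042197,
      "sd": 1.91177960531786
    },
    {
      "weight": 0.0569516321854817,
      "mean": 134.670635683551,
      "sd": 1.70241303439252
    },
    {
      "weight": 0.0707177026018084,
      "mean": 143.748523781874,
      "sd": 2.31266820384189
    },
    {
      "weight": 0.0427998495161746,
      "mean": 152.661659891407,
      "sd": 2.1420319871977
    },
    {
      "weight": 0.0457133863324289,
      "mean": 161.835297279592,
      "sd": 1.77687330706976
    },
    {
      "weight": 0.0182160771856299,
      "mean": 170.783279978981,
      "sd": 1.60355600714684
    },
    {
      "weight": 0.0832489607361959,
      "mean": 179.648229519704,
      "sd": 1.75600275443867
    },
    {
      "weight": 0.0308064818241802,
      "mean": 190.400510679576,
      "sd": 1.55785894882865
    }
  ]
}
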