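{
  "kind": "synthetic_gmm_target",
  "Ns": 200,
  "m": 3,
  "seed": 11,
  "sd_range": [2, 6],
  "min_frac": 0.2,
  "components": [
    {
      "weight": 0.580252373875839,
      "mean": 45.544995884411,
      "sd": 2.05619163345546
    },
    {
      "weight": 0.326424664578018,
      "mean": 90.0103662582114,
      "sd": 2.25875910650939
    },
    {
      "weight": 0.0933229615461433,
      "mean": 150.21216745954,
      "sd": 5.81939690187573
    }
  ]
}
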