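{
  "name": "DX_SCNP",
  "description": "Locked two-node apoptosis classifier for CR/CRi vs RD after cytarabine-based induction in elderly AML. Score = plogis(intercept + c1*C1 + c2*C2) with hinge-squared transforms of the two 24-hour AraC+Dauno Uu node metrics.",
  "version": "1.0",
  "intercept": -1.26004,
  "components": [
    {
      "id": "C1",
      "coefficient": 95.60133,
      "transform": "(N - 0.5)^2 if N > 0.5 else 0",
      "node": {"modulator": "AraC+Dauno", "time_hr": 24, "readout": "cPARP", "metric": "Uu"}
    },
    {
      "id": "C2",
      "coefficient": 34.94358,
      "transform": "(0.5 - N)^2 if N < 0.5 else 0",
      "node": {"modulator": "AraC+Dauno", "time_hr": 24, "readout": "CD34", "metric": "Uu"}
    }
  ]
}
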