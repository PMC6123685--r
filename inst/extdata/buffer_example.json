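{
  "_comment": "ILLUSTRATIVE constants only — apparent EGTA affinity depends strongly on pH, ionic strength and temperature; supply values measured or tabulated for your own assay conditions.",
  "chelators": [
    {
      "name": "EGTA",
      "total_M": 0.01,
      "Kd_Ca_M": 1.5e-7,
      "Kd_Mg_M": 9.0e-3
    }
  ],
  "total_Ca_M": 0.005,
  "total_Mg_M": 0.001,
  "pH": 7.0,
  "mode": "apparent"
}
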