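{
  "awake": 11,
  "ketamine": 0,
  "light_propofol": 4,
  "deep_propofol": 0,
  "light_sevoflurane": 3,
  "deep_sevoflurane": 0,
  "light_anaesthesia": 3,
  "deep_anaesthesia": 0,
  "dbs_off": 0,
  "ct_low": 3,
  "ct_high": 9,
  "vt_low": 0,
  "vt_high": 0
}
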