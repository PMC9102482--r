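{
  "S1":  {"SMP": "S1", "SMP3": "S2",  "SMP5": "S3"},
  "S2":  {"SMP": "S1", "SMP3": "S1",  "SMP5": "DUR"},
  "S3":  {"SMP": "S1", "SMP3": "DUR", "SMP5": "S4"},
  "S4":  {"SMP": "S1", "SMP3": "DUL", "SMP5": "S1"},
  "DUR": {"SMP": "S1", "SMP3": "DDR", "SMP5": "DUL"},
  "DUL": {"SMP": "S1", "SMP3": "DDL", "SMP5": "S2"},
  "DDR": {"SMP": "S1", "SMP3": "S3",  "SMP5": "DDL"},
  "DDL": {"SMP": "S1", "SMP3": "S4",  "SMP5": "S1"}
}
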