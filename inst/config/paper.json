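{
  "learning_rate": 0.0003,
  "batch_size": 5000,
  "epochs": 30,
  "lambda3": 0.1
}
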