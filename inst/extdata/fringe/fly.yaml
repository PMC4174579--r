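identity: Fng
cis_factor:
  Delta: 2.0
  Serrate: 0.2
trans_factor:
  Delta: 2.0
  Serrate: 0.2
detection_gain: 1.5
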