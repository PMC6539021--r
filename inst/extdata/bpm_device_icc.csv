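device,icc_pct
iHealth Clear,91
iHealth Track,90
Withings BPM,95
iHealth View,96
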