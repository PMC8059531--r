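"locality","lat","lon"
"Helgoland",54.18,7.88
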