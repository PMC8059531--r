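"old_name","accepted_name"
"Gibbula cineraria","Steromphala cineraria"
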