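"species","category"
"Carcinus maenas","very abundant"
"Asterias rubens","relatively common"
"Mytilus edulis","very abundant"
"Steromphala cineraria","rare"
"Crepidula fornicata","relatively common"
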