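"species","is_infauna","mean_size_cm"
"Mya arenaria",TRUE,8
"Ensis ensis",TRUE,12
"Parvicardium minimum",FALSE,0.8
"Mytilus edulis",FALSE,5
"Carcinus maenas",FALSE,6
"Asterias rubens",FALSE,15
"Steromphala cineraria",FALSE,1.5
"Crepidula fornicata",FALSE,4
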