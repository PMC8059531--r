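{"type":"FeatureCollection","features":[{"type":"Feature","properties":{},"geometry":{"type":"Polygon","coordinates":[[[1,54],[4,54],[4,56],[1,56],[1,54]]]}}]}
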