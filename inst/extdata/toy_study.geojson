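{"type":"FeatureCollection","features":[{"type":"Feature","properties":{},"geometry":{"type":"Polygon","coordinates":[[[0,50],[10,50],[10,56],[0,56],[0,50]]]}}]}
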