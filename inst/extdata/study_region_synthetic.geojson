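{"type":"FeatureCollection","features":[{"type":"Feature","properties":{},"geometry":{"type":"Polygon","coordinates":[[[1,51],[9,51],[9,53],[15,53],[15,56.5],[12,56.5],[12,58.5],[1,58.5],[1,51]]]}}]}
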