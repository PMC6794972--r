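paste,condition,r
EB@TiO2,WS,0.7762
EB@TiO2,S,0.9500
Colgate Pro-relief,WS,0.4230
Colgate Pro-relief,S,0.3558
Sensodyne repair,WS,0.2646
Sensodyne repair,S,0.4635
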