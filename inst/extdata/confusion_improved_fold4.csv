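actual,RNN,KNN,RF,LR
I,1636,1556,34,0
N,314,2386,25,0
D,1653,6690,39,0
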