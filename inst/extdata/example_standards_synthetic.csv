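id,rt_min,literature_index
std1,0.82,15.2
std2,1.45,28.9
std3,2.10,42.7
std4,2.74,55.8
std5,3.32,68.1
std6,3.95,81.6
std7,4.51,93.4
std8,5.08,105.9
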