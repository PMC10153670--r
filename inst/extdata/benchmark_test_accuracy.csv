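approach,Liver,Breast cancer,PIMA,Iris,Wine
SpikeProp,65.1,97.2,76.2,96.7,96.8
SWAT,60.9,95.8,72.1,92.4,92.3
SRESN,59.7,97.2,69.9,97.3,91.0
TMM-SNN,70.4,97.2,78.1,97.2,97.5
GE-SNN,67.2,95.9,74.8,93.9,86.8
ANN,71.8,97.1,77.4,97.1,99.1
C-STNet,69.0,97.1,78.2,97.7,98.8
P-STNet,72.0,97.3,77.4,97.6,99.1
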