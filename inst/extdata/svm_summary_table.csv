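kernel,sen,spe,ppv,acc,dice
linear,87.88,87.35,93.38,87.69,0.90
rbf,92.44,95.91,97.93,93.62,0.95
poly2,90.39,98.18,99.06,93.01,0.94
poly3,89.48,98.18,99.02,92.41,0.94
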