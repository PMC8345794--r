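kernel,fold,tp,tn,fp,fn,acc,ppv,sen,spe,dice
linear,1,37,21,1,6,89.23,97.37,86.05,95.45,0.91
linear,2,41,19,4,2,90.91,91.11,95.35,82.61,0.93
linear,3,38,17,5,6,83.33,88.37,86.36,77.27,0.87
linear,4,40,21,1,4,92.42,97.56,90.91,95.45,0.94
linear,5,39,17,5,5,84.85,88.64,88.64,77.27,0.89
linear,6,39,18,4,5,86.36,90.70,88.64,81.82,0.90
linear,7,40,19,3,4,89.39,93.02,90.91,86.36,0.92
linear,8,36,20,2,8,84.85,94.74,81.82,90.91,0.88
linear,9,38,20,2,6,87.88,95.00,86.36,90.91,0.90
linear,10,36,21,1,7,87.69,97.30,83.72,95.45,0.90
poly2,1,37,22,0,6,90.77,100.00,86.05,100.00,0.93
poly2,2,39,23,0,4,93.94,100.00,90.70,100.00,0.95
poly2,3,40,20,2,4,90.91,95.24,90.91,90.91,0.93
poly2,4,39,22,0,5,92.42,100.00,88.64,100.00,0.94
poly2,5,43,21,1,1,96.97,97.73,97.73,95.45,0.98
poly2,6,40,22,0,4,93.94,100.00,90.91,100.00,0.95
poly2,7,41,21,1,3,93.94,97.62,93.18,95.45,0.95
poly2,8,36,22,0,8,87.88,100.00,81.82,100.00,0.90
poly2,9,40,22,0,4,93.94,100.00,90.91,100.00,0.95
poly2,10,40,22,0,3,95.38,100.00,93.02,100.00,0.96
poly3,1,38,22,0,5,92.31,100.00,88.37,100.00,0.94
poly3,2,38,23,0,5,92.42,100.00,88.37,100.00,0.94
poly3,3,40,21,1,4,92.42,97.56,90.91,95.45,0.94
poly3,4,39,22,0,5,92.42,100.00,88.64,100.00,0.94
poly3,5,42,21,1,2,95.45,97.67,95.45,95.45,0.97
poly3,6,41,22,0,3,95.45,100.00,93.18,100.00,0.96
poly3,7,38,20,2,6,87.88,95.00,86.36,90.91,0.90
poly3,8,37,22,0,7,89.39,100.00,84.09,100.00,0.91
poly3,9,37,22,0,7,89.39,100.00,84.09,100.00,0.91
poly3,10,41,22,0,2,96.92,100.00,95.35,100.00,0.98
rbf,1,38,21,1,5,90.77,97.44,88.37,95.45,0.93
rbf,2,40,23,0,3,95.45,100.00,93.02,100.00,0.96
rbf,3,41,18,4,3,89.39,91.11,93.18,81.82,0.92
rbf,4,40,22,0,4,93.94,100.00,90.91,100.00,0.95
rbf,5,43,20,2,1,95.45,95.56,97.73,90.91,0.97
rbf,6,40,21,1,4,92.42,97.56,90.91,95.45,0.94
rbf,7,42,21,1,2,95.45,97.67,95.45,95.45,0.97
rbf,8,39,22,0,5,92.42,100.00,88.64,100.00,0.94
rbf,9,41,22,0,3,95.45,100.00,93.18,100.00,0.96
rbf,10,40,22,0,3,95.38,100.00,93.02,100.00,0.96
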