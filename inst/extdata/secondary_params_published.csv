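extract,r2_arrhenius,ea_j_mol,k0_per_day,r2_loglogistic,c_per_c,tc_c
control,0.9972,60292,1.7e11,0.9955,0.1094,21.73
allspice,0.9794,118544,4.7e20,0.9973,0.1615,26.53
basil,0.9896,94708,3.9e16,0.9786,0.1357,23.36
bay leaf,0.9718,88610,3.37e15,0.9779,0.1495,29.48
black seed,0.9857,131842,2.2e23,0.9971,0.1827,21.74
cardamom,0.9972,76564,2.1e13,0.9966,0.1288,24.13
caraway,0.8868,27250,1.4e4,0.8832,0.0442,54.87
clove,0.9891,-122721,3.8e8,0.9867,0.1514,57.87
garlic,0.9941,63945,1.2e11,0.9963,0.1121,24.11
nutmeg,0.9965,61056,2.2e10,0.9929,0.0932,32.57
onion,0.9979,79215,8.9e13,0.9948,0.1433,20.09
oregano,0.9963,105249,3.5e18,0.9996,0.1695,21.24
rosemary,0.9495,95558,6.9e16,0.9957,0.1024,28.75
thyme,0.9916,76348,1.7e13,0.9840,0.1123,26.09
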