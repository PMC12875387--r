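treatment,harvest,gwp
W0N0,1,250.41
W0N0,2,89.96
W0N0,3,50.36
W0N1,1,675.13
W0N1,2,281.06
W0N1,3,95.24
W0N2,1,1095.72
W0N2,2,497.69
W0N2,3,134.33
W0N3,1,1497.71
W0N3,2,748.41
W0N3,3,208.08
W1N0,1,379.26
W1N0,2,189.05
W1N0,3,149.80
W1N1,1,826.17
W1N1,2,404.76
W1N1,3,193.78
W1N2,1,1246.94
W1N2,2,616.32
W1N2,3,243.55
W1N3,1,1707.59
W1N3,2,883.49
W1N3,3,331.94
W2N0,1,648.73
W2N0,2,363.30
W2N0,3,300.72
W2N1,1,1101.53
W2N1,2,607.41
W2N1,3,344.54
W2N2,1,1559.97
W2N2,2,831.82
W2N2,3,431.41
W2N3,1,1979.94
W2N3,2,1173.25
W2N3,3,568.35
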