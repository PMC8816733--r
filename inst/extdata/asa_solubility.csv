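f1,T_C,C_molar,sd,analyte
0,25,0.0246,0.00059999999999999995,primary_solute
0.10000000000000001,25,0.034700000000000002,0.0011000000000000001,primary_solute
0.20000000000000001,25,0.059200000000000003,0.0025000000000000001,primary_solute
0.30000000000000004,25,0.128,0,primary_solute
0.40000000000000002,25,0.27100000000000002,0.0050000000000000001,primary_solute
0.5,25,0.43099999999999999,0.002,primary_solute
0.60000000000000009,25,0.54600000000000004,0.014,primary_solute
0.70000000000000007,25,0.68200000000000005,0.0030000000000000001,primary_solute
0.80000000000000004,25,0.77700000000000002,0.002,primary_solute
0.90000000000000002,25,0.86799999999999999,0.051999999999999998,primary_solute
1,25,0.82599999999999996,0.023,primary_solute
0,37,0.030800000000000001,0,primary_solute
0.10000000000000001,37,0.052200000000000003,0.0001,primary_solute
0.20000000000000001,37,0.10100000000000001,0,primary_solute
0.30000000000000004,37,0.20399999999999999,0.0040000000000000001,primary_solute
0.40000000000000002,37,0.40899999999999997,0.0030000000000000001,primary_solute
0.5,37,0.67100000000000004,0.0080000000000000002,primary_solute
0.60000000000000009,37,0.81599999999999995,0.091999999999999998,primary_solute
0.70000000000000007,37,0.995,0.016,primary_solute
0.80000000000000004,37,1.0600000000000001,0.19,primary_solute
0.90000000000000002,37,1.1299999999999999,0.080000000000000002,primary_solute
1,37,0.98799999999999999,0.002,primary_solute
0,25,0.00072599999999999997,1.2e-05,degradation_product
0.10000000000000001,25,0.00087799999999999998,6.3e-05,degradation_product
0.20000000000000001,25,0.0010399999999999999,9.0000000000000006e-05,degradation_product
0.30000000000000004,25,0.0019499999999999999,0,degradation_product
0.40000000000000002,25,0.0018600000000000001,0,degradation_product
0.5,25,0.00298,0,degradation_product
0.60000000000000009,25,0.00316,0,degradation_product
0.70000000000000007,25,0.0036700000000000001,5.0000000000000002e-05,degradation_product
0.80000000000000004,25,0.0032799999999999999,0.00072999999999999996,degradation_product
0.90000000000000002,25,0.0037299999999999998,0,degradation_product
1,25,0.0033800000000000002,0.00051999999999999995,degradation_product
0,37,0.0032000000000000002,0.00012999999999999999,degradation_product
0.10000000000000001,37,0.00447,0.00025000000000000001,degradation_product
0.20000000000000001,37,0.0077799999999999996,0.00059999999999999995,degradation_product
0.30000000000000004,37,0.0184,0,degradation_product
0.40000000000000002,37,0.032399999999999998,0,degradation_product
0.5,37,0.043099999999999999,0,degradation_product
0.60000000000000009,37,0.045199999999999997,0,degradation_product
0.70000000000000007,37,0.0533,0,degradation_product
0.80000000000000004,37,0.055199999999999999,0.0044000000000000003,degradation_product
0.90000000000000002,37,0.049399999999999999,0.0001,degradation_product
1,37,0.052400000000000002,0.0001,degradation_product
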