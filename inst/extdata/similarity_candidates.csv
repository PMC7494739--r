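comp_id,SP_A,SP_B,XP_A,XP_B,AD_A,AD_B,AVG,AI_Pred,IC50_uM
2,-10.25,-10.39,-11.06,-11.07,-8.1,-8.1,-9.83,1,2.32
3,-10.22,-10.28,-10.92,-10.91,-9,-9,-10.06,1,2.48
4,-9.51,-7.27,-10.58,-10.68,-11.7,-11.7,-10.24,1,18.04
5,-10.32,-10.52,-11.25,-11.88,-9.4,-9.4,-10.46,1,23.75
6,-9.95,-10.12,-11.84,-11.03,-11.2,-11.2,-10.89,0,NA
7,-9.9,-9.93,-11.81,-11.01,-7.9,-7.9,-9.74,0,NA
8,-9.26,-9.66,-10.26,-10.53,-9.9,-9.9,-9.92,1,NA
9,-9.66,-9.6,-11.26,-11.57,-10,-10,-10.35,1,NA
10,-9.7,-9.33,-10.95,-10.95,-10.1,-10.1,-10.19,1,NA
11,-9.36,-6.19,-8.65,-8.89,-9.4,-9.4,-8.65,1,NA
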