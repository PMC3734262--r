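scope,n,gene,mean,sd,cv,slope,intercept,si
RCF,20,FaRIB413,8.341,0.239,2.860,0.004,8.329,0.011
RCF,20,FaCHC1,23.085,0.201,0.869,0.021,23.024,0.018
RCF,20,FaTUBb,22.334,0.359,1.609,0.015,22.289,0.024
RCF,20,FaACTIN,23.894,0.309,1.294,0.144,24.326,0.186
RCF,20,FaTIM1,22.602,0.359,1.587,0.151,23.054,0.239
RCF,20,FaMT1,25.622,0.449,1.753,0.143,25.193,0.251
RCF,20,FaEF1a,17.406,0.413,2.371,0.161,17.889,0.382
RCF,20,FaFHA1,23.258,0.643,2.765,0.204,23.870,0.564
RCF,20,FaTUBa,22.899,1.174,5.128,0.556,24.567,2.851
RCF,20,FaBZIP1,30.089,1.485,4.936,0.607,28.270,2.994
RCF,20,FaUBQ1,26.677,1.249,4.680,0.812,29.113,3.800
RCF,20,FaGAPDH2,17.073,1.071,6.274,0.622,18.939,3.903
RCF,20,FaGAPDH1,24.080,1.715,7.120,1.115,27.425,7.939
FCF,20,FaGAPDH1,23.530,0.316,1.345,0.005,23.545,0.007
FCF,20,FaTUBa,21.462,0.322,1.499,0.019,21.518,0.028
FCF,20,FaUBQ1,25.599,0.405,1.583,0.047,25.458,0.074
FCF,20,FaGAPDH2,16.274,0.331,2.031,0.062,16.090,0.125
FCF,20,FaACTIN,23.539,0.314,1.335,0.136,23.133,0.181
FCF,20,FaEF1a,16.556,0.250,1.510,0.130,16.166,0.196
FCF,20,FaTIM1,24.031,0.372,1.549,0.131,23.638,0.203
FCF,20,FaCHC1,23.929,0.467,1.953,0.121,23.568,0.235
FCF,20,FaTUBb,21.668,0.387,1.784,0.133,21.271,0.236
FCF,20,FaBZIP1,27.780,0.478,1.719,0.164,27.288,0.282
FCF,20,FaFHA1,23.606,0.545,2.308,0.213,22.969,0.490
FCF,20,FaRIB413,8.635,0.323,3.736,0.158,8.161,0.590
FCF,20,FaMT1,25.910,0.745,2.876,0.425,24.635,1.222
FCC,32,FaUBQ1,27.734,0.486,1.752,0.037,27.567,0.065
FCC,32,FaRIB413,7.873,0.241,3.057,0.027,7.752,0.083
FCC,32,FaGAPDH1,25.569,0.453,1.771,0.064,25.282,0.113
FCC,32,FaCHC1,24.988,0.492,1.968,0.067,24.687,0.131
FCC,32,FaEF1a,17.786,0.386,2.173,0.062,17.509,0.134
FCC,32,FaGAPDH2,19.286,0.352,1.825,0.090,18.880,0.165
FCC,32,FaMT1,22.968,0.571,2.486,0.068,22.664,0.168
FCC,32,FaFHA1,23.875,0.651,2.728,0.062,24.156,0.170
FCC,32,FaTIM1,25.885,0.813,3.139,0.116,25.363,0.364
FCC,32,FaTUBb,22.086,0.622,2.818,0.136,21.472,0.384
FCC,32,FaTUBa,20.298,0.585,2.883,0.136,19.687,0.392
FCC,32,FaACTIN,24.440,0.563,2.303,0.211,23.493,0.485
FCC,32,FaBZIP1,25.229,0.929,3.682,0.279,23.975,1.026
FCP,32,FaTUBa,20.767,0.423,2.036,0.007,20.737,0.014
FCP,32,FaACTIN,23.676,0.364,1.536,0.013,23.528,0.020
FCP,32,FaRIB413,8.816,0.237,2.685,0.027,8.695,0.072
FCP,32,FaBZIP1,24.874,0.620,2.493,0.034,25.025,0.084
FCP,32,FaEF1a,17.574,0.437,2.485,0.034,17.727,0.084
FCP,32,FaGAPDH2,18.321,0.357,1.946,0.064,18.611,0.125
FCP,32,FaMT1,22.583,0.517,2.288,0.065,22.293,0.148
FCP,32,FaTUBb,22.009,0.574,2.609,0.100,21.561,0.260
FCP,32,FaCHC1,24.874,0.735,2.954,0.139,25.499,0.411
FCP,32,FaUBQ1,27.470,0.766,2.788,0.169,28.246,0.472
FCP,32,FaTIM1,25.223,0.755,2.993,0.193,26.091,0.577
FCP,32,FaFHA1,24.264,0.774,3.191,0.224,25.270,0.713
FCP,32,FaGAPDH1,25.419,1.120,4.405,0.263,26.600,1.156
FAP,28,FaGAPDH1,26.129,0.632,2.418,0.004,26.143,0.009
FAP,28,FaGAPDH2,18.484,0.374,2.024,0.025,18.585,0.051
FAP,28,FaACTIN,23.640,0.428,1.812,0.030,23.760,0.054
FAP,28,FaEF1a,18.780,0.417,2.219,0.026,18.886,0.059
FAP,28,FaMT1,23.992,0.506,2.108,0.028,23.879,0.060
FAP,28,FaFHA1,24.251,0.570,2.349,0.036,24.107,0.085
FAP,28,FaTUBb,21.575,0.374,1.734,0.090,21.216,0.155
FAP,28,FaCHC1,26.339,0.404,1.536,0.120,26.816,0.184
FAP,28,FaBZIP1,26.410,0.446,1.688,0.110,25.971,0.185
FAP,28,FaTIM1,26.864,0.481,1.790,0.116,26.401,0.207
FAP,28,FaUBQ1,27.650,0.642,2.322,0.115,27.085,0.266
FAP,28,FaRIB413,8.790,0.444,5.053,0.061,9.036,0.310
FAP,28,FaTUBa,20.281,0.595,2.931,0.211,19.436,0.620
HCY,36,FaGAPDH1,25.817,0.479,1.856,0.024,25.938,0.045
HCY,36,FaUBQ1,28.954,0.518,1.789,0.026,29.085,0.047
HCY,36,FaGAPDH2,19.183,0.278,1.451,0.038,18.993,0.055
HCY,36,FaRIB413,8.838,0.523,5.912,0.016,8.760,0.093
HCY,36,FaCHC1,26.297,0.482,1.832,0.080,25.895,0.147
HCY,36,FaTUBa,23.058,0.586,2.542,0.093,22.591,0.237
HCY,36,FaFHA1,25.649,0.615,2.396,0.101,25.145,0.242
HCY,36,FaEF1a,18.593,0.442,2.375,0.119,17.996,0.284
HCY,36,FaMT1,25.669,0.726,2.829,0.165,24.846,0.466
HCY,36,FaTIM1,27.336,0.800,2.928,0.176,26.457,0.514
HCY,36,FaTUBb,23.573,0.775,3.286,0.218,22.484,0.716
HCY,36,FaBZIP1,27.459,0.845,3.079,0.262,26.150,0.806
HCY,36,FaACTIN,25.122,0.979,3.899,0.325,23.499,1.265
HCC,24,FaTIM1,25.850,0.974,3.766,0.003,25.862,0.013
HCC,24,FaGAPDH2,17.889,0.300,1.679,0.013,17.843,0.022
HCC,24,FaRIB413,8.426,0.299,3.551,0.021,8.498,0.073
HCC,24,FaUBQ1,27.222,0.566,2.079,0.039,27.322,0.081
HCC,24,FaCHC1,24.163,0.427,1.767,0.129,23.712,0.228
HCC,24,FaBZIP1,25.344,0.523,2.063,0.163,25.914,0.336
HCC,24,FaEF1a,16.478,0.413,2.505,0.151,15.950,0.377
HCC,24,FaTUBa,20.364,0.539,2.649,0.236,19.538,0.625
HCC,24,FaMT1,24.533,0.550,2.240,0.282,23.545,0.632
HCC,24,FaFHA1,23.116,0.612,2.646,0.246,22.256,0.650
HCC,24,FaACTIN,23.145,0.776,3.352,0.343,21.943,1.151
HCC,24,FaGAPDH1,20.908,0.836,3.999,0.401,22.313,1.605
HCC,24,FaTUBb,20.592,0.964,4.681,0.436,19.067,2.040
all,192,FaACTIN,24.011,0.883,3.676,0.004,23.905,0.015
all,192,FaRIB413,8.542,0.490,5.736,0.056,8.306,0.323
all,192,FaTUBb,22.073,1.067,4.835,0.069,22.252,0.333
all,192,FaEF1a,17.716,0.904,5.100,0.082,17.270,0.416
all,192,FaMT1,24.338,1.399,5.747,0.097,24.857,0.560
all,192,FaFHA1,24.140,1.037,4.298,0.144,23.426,0.619
all,192,FaTUBa,21.292,1.305,6.131,0.158,21.937,0.970
all,192,FaGAPDH1,24.722,1.856,7.509,0.157,25.119,1.175
all,192,FaUBQ1,27.492,1.134,4.124,0.295,26.149,1.217
all,192,FaGAPDH2,18.270,1.063,5.818,0.267,17.007,1.551
all,192,FaCHC1,25.000,1.189,4.756,0.333,23.479,1.583
all,192,FaBZIP1,26.547,1.789,6.741,0.489,28.697,3.297
all,192,FaTIM1,25.650,1.591,6.201,0.619,22.923,3.839
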