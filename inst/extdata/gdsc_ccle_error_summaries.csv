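test_cohort,drug,model,min,q1,median,q3,max
GDSC,Sorafenib,shared,0.307,0.741,1.07,1.347,2.18
GDSC,Sorafenib,alone,0.394,0.857,1.12,1.419,2.2
GDSC,Erlotinib,shared,0.196,0.477,0.593,0.742,1.042
GDSC,Erlotinib,alone,0.221,0.578,0.729,0.945,1.467
GDSC,PHA-665752,shared,0.221,0.672,0.982,1.438,2.546
GDSC,PHA-665752,alone,0.324,0.81,1.182,1.652,2.881
GDSC,Nilotinib,shared,0.362,0.819,1.129,1.302,2.027
GDSC,Nilotinib,alone,0.488,0.92,1.131,1.34,1.928
GDSC,lapatinib,shared,0.117,0.332,0.632,0.799,1.298
GDSC,lapatinib,alone,0.092,0.532,0.915,1.196,2.041
GDSC,Nutlin-3,shared,0.392,0.602,0.726,0.82,1.12
GDSC,Nutlin-3,alone,0.747,1.016,1.144,1.271,1.644
GDSC,PLX4720,shared,0.384,0.676,0.836,1.045,1.488
GDSC,PLX4720,alone,0.386,0.699,0.86,1.155,1.805
GDSC,Crizotinib,shared,0.256,0.576,1.071,1.798,3.464
GDSC,Crizotinib,alone,0.392,0.785,1.05,1.516,2.453
GDSC,PD-0332991,shared,0.563,0.894,1.025,1.151,1.486
GDSC,PD-0332991,alone,0.722,1.036,1.214,1.372,1.815
GDSC,AZD0530,shared,0.339,0.764,0.959,1.182,1.727
GDSC,AZD0530,alone,0.33,0.755,0.922,1.155,1.734
GDSC,TAE684,shared,0.3,0.641,0.815,0.987,1.453
GDSC,TAE684,alone,0.285,0.778,0.981,1.174,1.744
GDSC,AZD6244,shared,0.554,0.819,0.946,1.085,1.46
GDSC,AZD6244,alone,0.536,0.857,0.987,1.119,1.436
GDSC,PD-0325901,shared,0.347,0.549,0.634,0.73,0.981
GDSC,PD-0325901,alone,0.408,0.56,0.641,0.74,0.996
GDSC,17-AAG,shared,0.417,0.59,0.666,0.741,0.947
GDSC,17-AAG,alone,0.485,0.689,0.777,0.861,1.115
GDSC,paclitaxel,shared,0.409,0.661,0.83,0.972,1.407
GDSC,paclitaxel,alone,0.321,0.696,0.9,1.165,1.736
CCLE,Sorafenib,shared,0.387,0.8234,1.025,1.372,2.074
CCLE,Sorafenib,alone,0.528,1.032,1.329,1.615,2.449
CCLE,Erlotinib,shared,0.150,0.569,0.736,0.970,1.493
CCLE,Erlotinib,alone,0.196,0.468,0.668,1.037,1.882
CCLE,PHA-665752,shared,0.273,0.770,1.141,1.486,2.498
CCLE,PHA-665752,alone,0.273,0.857,1.214,1.745,2.967
CCLE,Nilotinib,shared,0.548,0.899,1.104,1.267,1.794
CCLE,Nilotinib,alone,0.603,1.048,1.200,1.367,1.761
CCLE,lapatinib,shared,0.211,0.514,0.690,0.923,1.457
CCLE,lapatinib,alone,0.290,0.726,1.001,1.230,1.878
CCLE,Nutlin-3,shared,0.508,0.786,0.936,1.097,1.554
CCLE,Nutlin-3,alone,0.520,0.892,1.047,1.204,1.582
CCLE,PLX4720,shared,0.444,0.807,0.925,1.055,1.418
CCLE,PLX4720,alone,0.352,0.772,0.938,1.159,1.691
CCLE,Crizotinib,shared,0.389,0.716,0.910,1.194,1.907
CCLE,Crizotinib,alone,0.415,0.749,0.897,1.154,1.726
CCLE,PD-0332991,shared,0.511,0.849,0.974,1.112,1.448
CCLE,PD-0332991,alone,0.512,1.016,1.235,1.405,1.960
CCLE,AZD0530,shared,0.332,0.687,0.887,1.102,1.689
CCLE,AZD0530,alone,0.311,0.653,0.821,1.135,1.795
CCLE,TAE684,shared,0.333,0.788,0.955,1.135,1.569
CCLE,TAE684,alone,0.326,0.812,1.01,1.192,1.719
CCLE,AZD6244,shared,0.435,0.638,0.706,0.818,1.062
CCLE,AZD6244,alone,0.457,0.853,0.997,1.149,1.587
CCLE,PD-0325901,shared,0.3,0.446,0.496,0.566,0.702
CCLE,PD-0325901,alone,0.408,0.587,0.68,0.752,0.984
CCLE,17-AAG,shared,0.425,0.604,0.686,0.76,0.967
CCLE,17-AAG,alone,0.492,0.728,0.826,0.922,1.209
CCLE,paclitaxel,shared,0.217,0.586,0.761,1.025,1.487
CCLE,paclitaxel,alone,0.329,0.636,0.906,1.182,1.889
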