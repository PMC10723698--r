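taxon,guild,land_use,leaf_litter_mode,leaf_litter_mean,leaf_litter_lo,leaf_litter_hi,algae_mode,algae_mean,algae_lo,algae_hi,trophic_level_mean,tef_d13C_mean,tef_d15N_mean
Tipulidae,detritivore,forest,0.033,0.471,0.005,0.973,0.213,0.070,0.002,0.249,1.979,0.967,2.466
Calamoceratidae,detritivore,forest,0.027,0.276,0.002,0.970,0.107,0.075,0.001,0.556,1.962,0.632,2.689
Decapoda,detritivore,forest,0.170,0.159,0.005,0.721,0.120,0.274,0.003,0.895,1.997,0.597,2.821
Tadpole,herbivore,forest,0.065,0.151,0.005,0.831,0.123,0.269,0.002,0.914,1.956,0.238,2.839
Hydropsychidae,omnivore,forest,0.025,0.360,0.004,0.927,0.349,0.139,0.005,0.522,2.171,0.852,2.733
Poecilidae,omnivore,forest,0.036,0.195,0.003,0.917,0.256,0.302,0.003,0.934,2.456,0.394,3.030
Libellulidae,carnivore,forest,0.041,0.281,0.002,0.964,0.126,0.155,0.002,0.914,2.226,0.830,2.823
Perlidae,carnivore,forest,0.557,0.259,0.002,0.967,0.025,0.139,0.002,0.925,2.116,0.676,2.864
Belostomatidae,carnivore,forest,0.802,0.358,0.002,0.952,0.124,0.129,0.003,0.822,2.304,0.934,2.752
Megaloptera,carnivore,forest,0.661,0.243,0.004,0.914,0.044,0.207,0.004,0.884,2.146,0.599,2.853
Tipulidae,detritivore,coffee,0.596,0.365,0.012,0.870,0.326,0.265,0.009,0.765,2.277,0.425,2.918
Calamoceratidae,detritivore,coffee,0.405,0.391,0.009,0.915,0.166,0.209,0.006,0.750,2.043,0.490,2.786
Decapoda,detritivore,coffee,0.222,0.311,0.006,0.917,0.026,0.214,0.004,0.829,1.952,0.606,2.914
Tadpole,herbivore,coffee,0.237,0.358,0.005,0.955,0.331,0.149,0.003,0.818,1.973,0.653,2.793
Hydropsychidae,omnivore,coffee,0.657,0.266,0.008,0.822,0.004,0.333,0.008,0.860,2.154,0.659,2.992
Poecilidae,omnivore,coffee,0.006,0.241,0.005,0.890,0.551,0.313,0.006,0.904,2.314,0.563,3.064
Libellulidae,carnivore,coffee,0.157,0.285,0.003,0.930,0.205,0.201,0.004,0.895,2.050,0.792,2.893
Perlidae,carnivore,coffee,0.613,0.307,0.004,0.920,0.081,0.202,0.004,0.858,1.986,0.821,2.763
Belostomatidae,carnivore,coffee,0.570,0.295,0.005,0.916,0.217,0.203,0.005,0.831,1.917,0.792,2.777
Megaloptera,carnivore,coffee,0.173,0.266,0.005,0.912,0.455,0.275,0.005,0.893,1.934,0.752,2.729
Tipulidae,detritivore,pasture,0.570,0.617,0.027,0.964,0.093,0.111,0.003,0.418,1.725,0.323,2.465
Calamoceratidae,detritivore,pasture,0.586,0.676,0.056,0.967,0.209,0.090,0.002,0.352,1.658,0.098,2.532
Decapoda,detritivore,pasture,0.026,0.352,0.010,0.902,0.141,0.244,0.006,0.776,1.821,0.650,2.701
Tadpole,herbivore,pasture,0.288,0.372,0.016,0.905,0.409,0.201,0.004,0.734,1.848,-0.024,2.925
Hydropsychidae,omnivore,pasture,0.022,0.574,0.016,0.933,0.238,0.130,0.004,0.426,1.730,0.441,2.624
Poecilidae,omnivore,pasture,0.300,0.351,0.012,0.872,0.004,0.279,0.008,0.807,2.747,0.044,3.094
Libellulidae,carnivore,pasture,0.362,0.322,0.014,0.799,0.105,0.223,0.005,0.721,1.692,0.510,2.731
Perlidae,carnivore,pasture,0.551,0.361,0.007,0.864,0.238,0.242,0.007,0.721,1.940,0.666,2.938
Belostomatidae,carnivore,pasture,0.071,0.289,0.016,0.841,0.456,0.206,0.005,0.765,1.698,0.299,2.661
Megaloptera,carnivore,pasture,0.040,0.354,0.012,0.911,0.095,0.205,0.003,0.779,2.026,0.290,2.837
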