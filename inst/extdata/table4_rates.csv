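cultivar,temp_c,rh_pct,attribute,k,k_sd,adj_r2,ea_kj_mol,ea_sd
Desirable,20,30,L,0.006,0.001,0.85,15.10,13.52
Desirable,30,30,L,0.012,0.008,0.98,15.10,13.52
Desirable,40,30,L,0.019,0.023,0.89,15.10,13.52
Desirable,20,30,h,0.032,0.001,0.95,29.16,8.08
Desirable,30,30,h,0.066,0.001,0.87,29.16,8.08
Desirable,40,30,h,0.157,0.037,0.91,29.16,8.08
Desirable,20,30,C,0.001,0.003,0.68,23.83,14.89
Desirable,30,30,C,0.011,0.006,0.91,23.83,14.89
Desirable,40,30,C,0.025,0.034,0.85,23.83,14.89
Desirable,20,50,L,0.013,0.003,0.94,11.33,16.02
Desirable,30,50,L,0.021,0.001,0.98,11.33,16.02
Desirable,40,50,L,0.040,0.009,0.94,11.33,16.02
Desirable,20,50,h,0.033,0.006,0.78,30.34,3.75
Desirable,30,50,h,0.082,0.012,0.93,30.34,3.75
Desirable,40,50,h,0.178,0.019,0.77,30.34,3.75
Desirable,20,50,C,0.018,0.013,0.80,16.23,22.95
Desirable,30,50,C,0.017,0.012,0.99,16.23,22.95
Desirable,40,50,C,0.047,0.007,0.90,16.23,22.95
Desirable,20,75,L,0.041,0.001,0.94,12.64,6.65
Desirable,30,75,L,0.039,0.043,0.92,12.64,6.65
Desirable,40,75,L,0.061,0.020,0.97,12.64,6.65
Desirable,20,75,h,0.045,0.009,0.82,40.87,1.25
Desirable,30,75,h,0.164,0.016,0.86,40.87,1.25
Desirable,40,75,h,0.474,0.021,0.97,40.87,1.25
Desirable,20,75,C,0.053,0.002,0.85,22.60,5.94
Desirable,30,75,C,0.077,0.002,0.77,22.60,5.94
Desirable,40,75,C,0.105,0.120,0.92,22.60,5.94
Desirable,20,80,L,0.156,0.116,0.95,10.77,12.96
Desirable,30,80,L,0.118,0.166,0.94,10.77,12.96
Desirable,40,80,L,0.348,0.076,0.96,10.77,12.96
Desirable,20,80,h,0.050,0.017,0.52,57.30,7.78
Desirable,30,80,h,0.324,0.028,0.89,57.30,7.78
Desirable,40,80,h,1.048,0.175,0.96,57.30,7.78
Desirable,20,80,C,0.268,0.005,0.89,24.86,4.56
Desirable,30,80,C,0.209,0.247,0.93,24.86,4.56
Desirable,40,80,C,0.402,0.013,0.95,24.86,4.56
Pawnee,20,30,L,0.010,0.003,0.89,22.10,0.19
Pawnee,30,30,L,0.014,0.006,0.93,22.10,0.19
Pawnee,40,30,L,0.017,0.010,0.88,22.10,0.19
Pawnee,20,30,h,0.039,0.005,0.85,20.08,1.69
Pawnee,30,30,h,0.052,0.006,0.76,20.08,1.69
Pawnee,40,30,h,0.140,0.021,0.83,20.08,1.69
Pawnee,20,30,C,0.008,0.009,0.63,23.32,8.24
Pawnee,30,30,C,0.016,0.021,0.81,23.32,8.24
Pawnee,40,30,C,0.040,0.011,0.86,23.32,8.24
Pawnee,20,50,L,0.006,0.006,0.97,15.27,6.76
Pawnee,30,50,L,0.031,0.002,0.99,15.27,6.76
Pawnee,40,50,L,0.039,0.002,0.99,15.27,6.76
Pawnee,20,50,h,0.027,0.005,0.78,27.51,4.77
Pawnee,30,50,h,0.081,0.007,0.85,27.51,4.77
Pawnee,40,50,h,0.127,0.014,0.97,27.51,4.77
Pawnee,20,50,C,0.014,0.002,0.92,12.81,1.38
Pawnee,30,50,C,0.035,0.002,0.99,12.81,1.38
Pawnee,40,50,C,0.053,0.010,0.99,12.81,1.38
Pawnee,20,75,L,0.043,0.001,0.86,10.26,0.29
Pawnee,30,75,L,0.060,0.028,0.93,10.26,0.29
Pawnee,40,75,L,0.064,0.005,0.97,10.26,0.29
Pawnee,20,75,h,0.054,0.007,0.92,37.61,0.92
Pawnee,30,75,h,0.130,0.020,0.86,37.61,0.92
Pawnee,40,75,h,0.492,0.005,0.99,37.61,0.92
Pawnee,20,75,C,0.069,0.020,0.82,14.89,6.77
Pawnee,30,75,C,0.082,0.013,0.66,14.89,6.77
Pawnee,40,75,C,0.110,0.014,0.92,14.89,6.77
Pawnee,20,80,L,0.153,0.005,0.82,18.00,0.71
Pawnee,30,80,L,0.231,0.034,0.97,18.00,0.71
Pawnee,40,80,L,0.412,0.122,0.95,18.00,0.71
Pawnee,20,80,h,0.171,0.018,0.97,37.44,3.83
Pawnee,30,80,h,0.312,0.003,0.90,37.44,3.83
Pawnee,40,80,h,0.959,0.121,0.84,37.44,3.83
Pawnee,20,80,C,0.243,0.058,0.95,8.70,6.74
Pawnee,30,80,C,0.351,0.031,0.95,8.70,6.74
Pawnee,40,80,C,0.385,0.051,0.94,8.70,6.74
Stuart,20,30,L,0.012,0.001,0.99,19.55,14.34
Stuart,30,30,L,0.020,0.007,0.98,19.55,14.34
Stuart,40,30,L,0.029,0.025,0.95,19.55,14.34
Stuart,20,30,h,0.043,0.006,0.99,26.19,3.75
Stuart,30,30,h,0.067,0.011,0.93,26.19,3.75
Stuart,40,30,h,0.166,0.016,0.92,26.19,3.75
Stuart,20,30,C,0.010,0.005,0.88,26.08,26.57
Stuart,30,30,C,0.024,0.016,0.93,26.08,26.57
Stuart,40,30,C,0.042,0.036,0.95,26.08,26.57
Stuart,20,50,L,0.008,0.001,0.88,19.38,2.16
Stuart,30,50,L,0.023,0.008,0.96,19.38,2.16
Stuart,40,50,L,0.041,0.004,0.97,19.38,2.16
Stuart,20,50,h,0.039,0.005,0.88,22.28,4.90
Stuart,30,50,h,0.087,0.014,0.87,22.28,4.90
Stuart,40,50,h,0.130,0.006,0.96,22.28,4.90
Stuart,20,50,C,0.021,0.003,0.76,25.87,13.87
Stuart,30,50,C,0.024,0.012,0.92,25.87,13.87
Stuart,40,50,C,0.039,0.042,0.90,25.87,13.87
Stuart,20,75,L,0.013,0.013,0.89,25.38,20.41
Stuart,30,75,L,0.037,0.007,0.97,25.38,20.41
Stuart,40,75,L,0.100,0.064,0.97,25.38,20.41
Stuart,20,75,h,0.045,0.011,0.80,42.75,5.41
Stuart,30,75,h,0.122,0.001,0.86,42.75,5.41
Stuart,40,75,h,0.489,0.040,0.99,42.75,5.41
Stuart,20,75,C,0.034,0.007,0.59,28.05,1.16
Stuart,30,75,C,0.042,0.046,0.87,28.05,1.16
Stuart,40,75,C,0.153,0.031,0.93,28.05,1.16
Stuart,20,80,L,0.182,0.018,0.91,6.53,3.14
Stuart,30,80,L,0.261,0.037,0.94,6.53,3.14
Stuart,40,80,L,0.287,0.036,0.97,6.53,3.14
Stuart,20,80,h,0.064,0.022,0.18,46.44,1.15
Stuart,30,80,h,0.325,0.039,0.95,46.44,1.15
Stuart,40,80,h,1.315,0.103,0.95,46.44,1.15
Stuart,20,80,C,0.386,0.006,0.95,7.63,1.40
Stuart,30,80,C,0.373,0.030,0.90,7.63,1.40
Stuart,40,80,C,0.431,0.025,0.94,7.63,1.40
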