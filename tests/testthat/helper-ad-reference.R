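# Frozen reference vectors for the k-sample Anderson-Darling test,
# with expected standardized statistic and p-value computed from an
# independent reference implementation of the midrank variant.

adRefA2 <- c(2.337758, 0.097105, 2.688443, 0.853355, 0.049758, 0.208607,
  1.140896, 0.564448, 1.192963, 0.281671, 0.149862, 0.371848, 0.281522,
  0.301436, 4.31031, 0.154272, 0.198049, 2.466261, 0.391539, 0.101448,
  0.56821, 0.717857, 0.539747, 0.092535, 2.071323, 0.175851, 0.86697,
  0.168819, 0.70302, 0.741149, 1.059997, 0.086603, 0.18143, 0.103589,
  0.681266, 0.022091, 0.523601, 0.091399, 0.066378, 0.108074, 0.155565,
  1.994164, 0.919101, 2.038492, 1.280772, 2.328718, 4.990588, 0.466506,
  0.291114, 0.231422, 3.455657, 0.117678, 5.588667, 0.422704, 0.8216,
  1.213382, 1.195223, 0.366786, 1.065349, 1.46685)

adRefB2 <- c(0.653888, 0.932394, 0.1532, 0.120289, 2.641001, 1.732091,
  8.59133, 0.103457, 0.045134, 0.591738, 0.430004, 0.652947, 0.449292,
  1.079392, 0.449274, 2.253748, 1.744809, 1.253281, 0.069302, 2.014755,
  1.28414, 2.163459, 6.085978, 0.918615, 0.269282, 1.382018, 0.689171,
  1.427846, 0.066225, 2.079176, 2.241232, 5.927962, 4.681585, 0.461865,
  2.202935, 1.174728, 1.093, 0.795066, 3.924404, 0.224833, 1.09911,
  0.23985, 0.075636, 0.060128, 1.619673, 1.591125, 0.052367, 3.338709,
  0.601433, 11.404332, 1.688893, 0.890089, 7.527062, 1.707311, 1.649235,
  1.619775, 1.679722, 1.152316, 0.877369, 0.697617)

adRefTm <- 3.99884402811453
adRefP <- 0.008078817141850696
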