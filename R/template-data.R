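# Frozen output of design_fold_template() on reference_interfaces();
# see that function for the objective. Coordinates in Angstrom, rows are
# residues 54-82, columns x, y, z.
.zf0_template <- matrix(c(
  -3.0972, 0.9051, 6.7757,
  -0.4104, 2.8387, 8.2819,
  -1.8554, -0.4036, 10.1068,
  0.6307, -2.6081, 12.0616,
  4.2497, -1.4931, 12.3764,
  4.8610, 2.1783, 11.6100,
  3.8705, 5.8411, 11.4042,
  6.5650, 4.9979, 13.9475,
  9.5297, 4.8362, 11.5760,
  11.0555, 4.5065, 8.1114,
  7.3559, 3.6790, 7.8509,
  6.7700, 7.4273, 8.0664,
  4.3521, 5.7916, 5.6337,
  3.8966, 2.1421, 4.6776,
  7.2790, 3.6379, 3.7656,
  8.7348, 2.7919, 0.3496,
  8.6052, 1.2497, -3.1299,
  5.5288, 2.9420, -1.6848,
  5.7698, 0.8327, 1.6946,
  1.7968, -0.6058, 3.2284,
  2.4390, 1.8711, 0.2402,
  2.5388, 5.2746, -1.4478,
  4.1348, 4.7945, 1.9726,
  0.6794, 3.4820, 3.1926,
  0.9613, 6.8475, 1.6303,
  -1.7852, 8.2772, 3.8332,
  -3.5952, 10.7166, 6.1165,
  0.1193, 10.3867, 6.8473,
  3.5372, 10.0082, 5.2303
), ncol = 3, byrow = TRUE,
  dimnames = list(as.character(54:82), c("x", "y", "z")))
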