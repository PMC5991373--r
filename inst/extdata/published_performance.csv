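algorithm,n_case,n_control,n_positive,sensitivity,sens_lower,sens_upper,specificity,spec_lower,spec_upper,ppv,ppv_lower,ppv_upper,npv,npv_lower,npv_upper
1,59,180,65,88.1,77.1,95.1,92.8,88.0,96.1,80.0,68.2,88.9,96.0,91.9,98.4
2,59,180,62,86.4,75.0,94.0,93.9,89.3,96.9,82.3,70.5,90.8,95.5,91.3,98.0
3,59,180,33,49.2,35.9,62.5,97.8,94.4,99.4,87.9,71.8,96.6,85.4,79.9,90.0
4,59,180,41,50.8,37.5,64.1,93.9,89.3,96.9,73.2,57.1,85.8,85.4,79.6,90.0
5,59,180,84,89.8,79.2,96.2,82.8,76.5,88.0,63.1,51.9,73.4,96.1,91.8,98.6
6,59,180,79,88.1,77.1,95.1,85.0,78.9,89.9,65.8,54.3,76.1,95.6,91.2,98.2
7,59,180,63,86.4,75.0,94.0,93.3,88.6,96.5,81.0,69.1,89.8,95.5,91.2,98.0
8,59,180,58,76.3,63.4,86.4,92.8,88.0,96.1,77.6,64.7,87.5,92.3,87.4,95.7
9,59,180,64,83.1,71.0,91.6,91.7,86.6,95.3,76.6,64.3,86.2,94.3,89.7,97.2
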