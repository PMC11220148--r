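position,subject,body_weight_N,total_pressure_N,F_z_N,F_x_N,F_y_N
supine,1,343.00,460.66,349.06,8.76,-5.72
supine,2,450.80,596.15,428.79,1.66,4.46
supine,3,617.40,814.46,619.64,12.78,-0.75
supine,4,676.20,843.18,655.41,-8.89,8.55
supine,5,735.00,892.29,714.88,2.08,12.56
lateral,1,343.00,445.74,333.68,1.32,-13.15
lateral,2,450.80,576.34,483.52,3.87,-11.17
lateral,3,617.40,872.18,685.99,-25.50,-10.84
lateral,4,676.20,837.21,655.41,-8.89,8.55
lateral,5,735.00,1020.84,607.53,-5.43,-49.22
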