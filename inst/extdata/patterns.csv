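id,n_components,component_ids,mean_v0,span,orientation
a,3,c2;c1;c5,24.000,2.00,157.52
b,3,c3;c1;c6,24.000,4.83,67.50
c,3,c4;c1;c7,24.000,6.27,27.86
d,3,c8;c1;c12,24.000,4.00,157.49
e,3,c9;c1;c13,24.000,7.31,75.36
f,3,c11;c1;c15,24.000,10.07,23.48
g,2,c1;c5,20.108,1.00,157.52
h,2,c2;c1,29.761,1.00,157.52
i,3,c10;c1;c14,24.000,7.84,45.00
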