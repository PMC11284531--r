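name,k,medium,note
trolox,1.30e5,water,M06-2X/6-311++G(d;p) value
trolox_m05,8.96e4,water,M05-2X/6-31+G(d;p) value
ascorbic_acid,9.97e7,water,M05-2X/6-311++G(d;p) value
resveratrol,5.62e7,water,M05-2X/6-31+G(d;p) value
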