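Out,F_1,F_2,F_3,F_4,F_5,F_6,F_7,F_8,F_9,F_10,F_11,F_12,F_13,F_14,F_15
YES,M,69,1,2,2,1,1,2,1,2,2,2,2,2,2
YES,M,74,2,1,1,1,2,2,2,1,1,1,2,2,2
NO,F,59,1,1,1,2,1,2,1,2,1,2,2,1,2
NO,M,63,2,2,2,1,1,1,1,1,2,1,1,2,2
NO,F,63,1,2,1,1,1,1,1,2,1,2,2,1,1
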