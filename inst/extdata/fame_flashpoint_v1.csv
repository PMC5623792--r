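label,fp_c
C12:0,113
C14:0,135
C16:0,148
C16:1,141
C17:1,150
C18:0,153
C18:1,163
C18:2,166
C18:3 n-3,163
C20:1 n-9,175
C20:3 n-6,170
C20:4 n-6,170
C22:2,182
C22:4,178
C24:0,190
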