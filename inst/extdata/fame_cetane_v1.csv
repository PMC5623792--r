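label,mw_fame,cn_me
C12:0,214.349,56.93
C14:0,242.403,65.41
C16:0,270.457,73.88
C16:1,268.441,53.27
C17:1,282.468,57.51
C18:0,298.511,82.35
C18:1,296.495,61.74
C18:2,294.479,41.13
C18:3 n-3,292.463,20.52
C20:1 n-9,324.549,70.21
C20:3 n-6,320.517,29
C20:4 n-6,318.501,8.39
C22:2,350.587,58.08
C22:4,346.555,16.86
C24:0,382.673,107.77
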