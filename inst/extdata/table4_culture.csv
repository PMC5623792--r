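strain,medium,biomass_g_l,lipids_g_l,duration_h,qx_printed,ql_printed
Candida inconspicua IG 11,YPGlc,12.2,4.04,96,0.127,0.042
Candida inconspicua IG 11,YPLac,13.5,3.38,96,0.141,0.035
Candida inconspicua IG 11,YPGly,9.8,1.71,96,0.102,0.018
Debaryomyces hansenii 1,YPGlc,13.5,6.31,96,0.140,0.066
Debaryomyces hansenii 1,YPLac,12.9,2.02,96,0.134,0.021
Debaryomyces hansenii 1,YPGly,11.8,2.26,96,0.123,0.024
Debaryomyces hansenii IG II,YPGlc,13.8,1.14,96,0.144,0.012
Debaryomyces hansenii IG II,YPLac,13.0,1.77,96,0.135,0.018
Debaryomyces hansenii IG II,YPGly,13.6,3.28,96,0.142,0.034
Debaryomyces hansenii IG 01,YPGlc,14.8,5.65,96,0.154,0.059
Debaryomyces hansenii IG 01,YPLac,10.7,1.78,96,0.111,0.018
Debaryomyces hansenii IG 01,YPGly,10.2,1.85,96,0.106,0.019
Kazachstania unispora IG 16,YPGlc,11.0,1.70,96,0.114,0.018
Kazachstania unispora IG 16,YPLac,10.4,1.32,96,0.108,0.014
Kazachstania unispora IG 16,YPGly,12.1,0.87,96,0.126,0.009
Kluyveromyces marxianus IG 1,YPGlc,12.9,3.71,96,0.134,0.039
Kluyveromyces marxianus IG 1,YPLac,12.2,4.76,96,0.127,0.049
Kluyveromyces marxianus IG 1,YPGly,10.7,0.50,96,0.111,0.005
Zygotorulaspora florentina IG 12,YPGlc,13.7,4.44,96,0.143,0.046
Zygotorulaspora florentina IG 12,YPLac,12.4,1.97,96,0.129,0.020
Zygotorulaspora florentina IG 12,YPGly,11.3,2.34,96,0.118,0.024
Candida inconspicua IG 11,DPWGlc,10.5,0.36,96,0.109,0.004
Candida inconspicua IG 11,DPWLac,10.9,1.58,96,0.113,0.016
Candida inconspicua IG 11,DPWGly,10.9,2.35,96,0.113,0.024
Debaryomyces hansenii 1,DPWGlc,12.3,1.12,96,0.128,0.012
Debaryomyces hansenii 1,DPWLac,11.6,1.99,96,0.121,0.021
Debaryomyces hansenii 1,DPWGly,11.0,1.79,96,0.112,0.018
Debaryomyces hansenii IG II,DPWGlc,11.7,0.85,96,0.122,0.009
Debaryomyces hansenii IG II,DPWLac,12.4,0.69,96,0.129,0.007
Debaryomyces hansenii IG II,DPWGly,10.8,1.92,96,0.112,0.020
Debaryomyces hansenii IG 01,DPWGlc,11.4,2.80,96,0.119,0.030
Debaryomyces hansenii IG 01,DPWLac,11.7,2.43,96,0.122,0.025
Debaryomyces hansenii IG 01,DPWGly,10.5,2.21,96,0.111,0.023
Kazachstania unispora IG 16,DPWGlc,9.9,0.79,96,0.103,0.008
Kazachstania unispora IG 16,DPWLac,11.6,1.91,96,0.121,0.019
Kazachstania unispora IG 16,DPWGly,10.3,2.22,96,0.107,0.023
Kluyveromyces marxianus IG 1,DPWGlc,10.3,3.56,96,0.108,0.037
Kluyveromyces marxianus IG 1,DPWLac,11.4,1.74,96,0.119,0.018
Kluyveromyces marxianus IG 1,DPWGly,10.7,2.16,96,0.111,0.022
Zygotorulaspora florentina IG 12,DPWGlc,10.1,0.52,96,0.105,0.005
Zygotorulaspora florentina IG 12,DPWLac,11.9,0.85,96,0.123,0.009
Zygotorulaspora florentina IG 12,DPWGly,11.1,1.97,96,0.115,0.020
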