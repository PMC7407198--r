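node,primary,aseptic,septic
p-CREB,0.96,0.77,1.15
p-HSP27,1.13,1.14,1.15
p-IkBa,1.13,1.16,1.10
p-MEK1,1.13,1.08,1.10
p-S6RP,1.13,0.98,1.13
p-Smad2,1.13,1.15,1.14
p-Src,1.13,1.15,1.15
p-Syk,1.13,1.11,0.95
p-c-Jun,1.04,0.77,1.03
p-AKT,1.10,0.99,1.08
p-p53,1.13,1.00,1.06
p-p38,1.13,1.05,1.06
p-p70S6K,1.13,1.15,1.07
p-PTEN,1.09,1.02,0.76
p-ZAP-70,1.13,1.16,1.07
p-BAD,0.96,0.77,1.15
p-ERK1/2,1.13,1.15,1.13
p-GSK-3a/b,1.13,1.16,1.12
p-p90RSK,1.13,0.99,1.04
p-VEGFR2,1.13,0.99,1.11
p-NF-kB,1.13,1.16,1.09
IL-1b,0.62,0.91,0.76
IL-4,0.90,1.01,0.76
IL-6,0.60,0.82,0.76
IL-1a,0.63,1.15,0.76
IL-10,0.73,0.79,1.02
IL-12p70,0.84,0.77,1.06
IL-13,0.84,0.77,0.76
IFN-y,0.85,0.96,0.76
TNF-a,0.85,0.93,0.76
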