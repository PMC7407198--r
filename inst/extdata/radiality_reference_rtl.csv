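node,primary,aseptic,septic
p-CREB,1.12,0.79,1.06
p-HSP27,0.87,1.12,1.03
p-IkBa,1.07,1.13,1.01
p-MEK1,0.99,1.05,1.08
p-S6RP,1.06,0.98,1.02
p-Smad2,1.12,1.11,1.10
p-Src,0.97,1.08,1.04
p-Syk,1.01,0.96,0.94
p-c-Jun,1.11,0.97,0.99
p-AKT,0.80,1.12,1.09
p-p53,0.97,1.07,1.00
p-p38,1.11,1.08,1.06
p-p70S6K,0.80,1.13,1.00
p-PTEN,1.12,1.12,1.05
p-ZAP-70,1.11,0.96,1.07
p-BAD,1.12,0.79,1.06
p-ERK1/2,0.83,1.09,1.11
p-GSK-3a/b,1.12,1.12,1.02
p-p90RSK,1.10,1.00,0.95
p-VEGFR2,1.09,1.13,1.10
p-NF-kB,1.04,1.12,1.04
IL-1b,0.85,0.99,1.08
IL-4,1.04,1.03,1.00
IL-6,0.82,0.89,1.11
IL-1a,0.84,1.09,1.11
IL-10,0.95,0.64,0.70
IL-12p70,0.96,0.92,1.07
IL-13,1.01,0.74,0.59
IFN-y,1.01,0.75,0.73
TNF-a,1.00,1.00,0.80
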