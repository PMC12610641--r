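compound,threshold,medium,source
1-Hexanol,0.74,air,VCF Online 16.10
α-Pinene,7.9,air,VCF Online 16.10
Sabinene,2,air,VCF Online 16.10
β-Pinene,0.14,water,VCF Online 16.10
β-Myrcene,0.061,air,VCF Online 16.10
Butyl butanoate,0.028,air,VCF Online 16.10
α-Terpinene,7.9,air,VCF Online 16.10
P-Cymene,7.2,air,VCF Online 16.10
D-Limonene,0.045,air,VCF Online 16.10
β-Phellandrene,0.5,air,VCF Online 16.10
β-Ocimene,0.034,water,VCF Online 16.10
γ-Terpinene,37.5,air,VCF Online 16.10
Terpinolene,0.2,air,VCF Online 16.10
Linalool,0.013,air,VCF Online 16.10
Nonanal,0.23,air,VCF Online 16.10
Terpinen-4-ol,0.59,air,VCF Online 16.10
Butyl caproate,0.7,air,VCF Online 16.10
α-Terpineol,0.41,air,VCF Online 16.10
β-Caryophyllene,1.5,air,VCF Online 16.10
Humulene,0.16,water,VCF Online 16.10
Elemol,0.1,air,VCF Online 16.10
E-Nerolidol,1.25,water,VCF Online 16.10
Caryophyllene oxide,2.4,air,VCF Online 16.10
γ-Dodecalactone,0.00481,air,VCF Online 16.10
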