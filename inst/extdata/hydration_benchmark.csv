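amino_acid,mimic,ddg_exp,ddg_bar,sem_bar,ddg_zwanzig,sem_zwanzig
ASN,Acetamide,11.62,11.18,0.06,11.18,0.06
CYS,Methanethiol,3.18,2.77,0.02,2.77,0.02
GLN,Propionamide,11.32,11.46,0.07,11.46,0.07
ILE,1-Butane,-0.21,0.13,0.05,0.13,0.05
LEU,Isobutane,-0.34,-0.04,0.02,-0.03,0.02
MET,Methylsulfanylethane,3.42,2.67,0.06,2.67,0.06
PHE,Toluene,2.70,3.47,0.04,3.47,0.04
SER,Methanol,7.00,6.99,0.05,6.98,0.05
THR,Ethanol,6.82,6.91,0.10,6.91,0.10
TRP,3-Methyl-1H-indole,7.82,7.72,0.08,7.72,0.08
TYR,p-Cresol,8.05,8.42,0.07,8.43,0.06
VAL,Propane,-0.05,0.08,0.02,0.08,0.02
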