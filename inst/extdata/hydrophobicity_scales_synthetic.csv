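residue,cyclohexane,octanol,ww_octanol_cor,ww_gxg,ww_popc_interface
ALA,-7.57,-1.30,-2.72,-2.72,0.71
ARG,62.43,4.23,2.76,2.76,3.39
ASN,40.50,2.51,-1.26,-1.26,1.76
ASP,36.48,3.22,10.42,10.42,5.15
CYS,-5.36,-6.44,-4.89,-4.89,-1.00
GLN,39.25,0.92,-1.59,-1.59,2.43
GLU,28.49,2.68,10.38,10.38,8.45
GLY,0.00,0.00,0.00,0.00,0.04
HIS,19.50,-0.54,-4.35,-4.35,0.71
ILE,-20.58,-7.53,-9.50,-9.50,-1.30
LEU,-20.58,-7.11,-10.04,-11.05,-2.34
LYS,23.22,4.14,6.90,6.90,4.14
MET,-9.83,-5.15,-7.61,-7.61,-0.96
PHE,-12.47,-7.49,-11.96,-11.96,-4.73
PRO,,-3.01,-4.23,-5.69,1.88
SER,21.17,0.17,-2.89,-2.89,0.54
THR,20.42,-1.09,-3.77,-3.77,0.59
TRP,9.75,-9.41,-13.56,-13.56,-7.74
TYR,0.59,-4.02,-7.78,-8.91,-3.93
VAL,-16.90,-5.10,-6.74,-7.74,0.29
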