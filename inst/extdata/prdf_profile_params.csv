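residue,species,charge_class,peak_height_molar,peak_pos_A,peak_width_A,depletion_depth_molar,decay_length_A,noise_sd_molar
ALA,Cl-,hydrophobic,0.8,3,1.3,0.836,3.945,0.02
ALA,K+,hydrophobic,0.8,3,1.3,0.836,3.945,0.02
ARG,Cl-,positive,1.3,3.2,1.4,0.05,1.6,0.02
ARG,K+,positive,1.3,3.2,1.4,0.05,1.6,0.02
ASN,Cl-,polar,0.8,3,1.3,0.827,3.906,0.02
ASN,K+,polar,0.8,3,1.3,0.827,3.906,0.02
ASP,Cl-,negative,1.3,2.6,1.2,1.413,4.2,0.02
ASP,K+,negative,1.3,2.6,1.2,1.413,4.2,0.02
CYS,Cl-,polar,0.8,3,1.3,0.147,1.6,0.02
CYS,K+,polar,0.8,3,1.3,0.147,1.6,0.02
GLN,Cl-,polar,0.8,3,1.3,0.263,1.652,0.02
GLN,K+,polar,0.8,3,1.3,0.263,1.652,0.02
GLU,Cl-,negative,1.2,2.8,1.2,1.301,4.2,0.02
GLU,K+,negative,1.2,2.8,1.2,1.301,4.2,0.02
GLY,Cl-,hydrophobic,0.8,3,1.3,0.305,1.82,0.02
GLY,K+,hydrophobic,0.8,3,1.3,0.305,1.82,0.02
HIS,Cl-,positive,0.6,3.4,1.4,1.518,4.2,0.02
HIS,K+,positive,0.6,3.4,1.4,1.518,4.2,0.02
ILE,Cl-,hydrophobic,0.8,3,1.3,0.945,4.2,0.02
ILE,K+,hydrophobic,0.8,3,1.3,0.945,4.2,0.02
LEU,Cl-,hydrophobic,0.8,3,1.3,1.234,4.2,0.02
LEU,K+,hydrophobic,0.8,3,1.3,1.234,4.2,0.02
LYS,Cl-,positive,1.1,3,1.3,0.836,3.946,0.02
LYS,K+,positive,1.1,3,1.3,0.836,3.946,0.02
MET,Cl-,hydrophobic,0.8,3,1.3,1.361,4.2,0.02
MET,K+,hydrophobic,0.8,3,1.3,1.361,4.2,0.02
PHE,Cl-,hydrophobic,0.8,3,1.3,0.827,3.909,0.02
PHE,K+,hydrophobic,0.8,3,1.3,0.827,3.909,0.02
PRO,Cl-,hydrophobic,0.8,3,1.3,0.985,4.2,0.02
PRO,K+,hydrophobic,0.8,3,1.3,0.985,4.2,0.02
SER,Cl-,polar,0.8,3,1.3,0.824,3.896,0.02
SER,K+,polar,0.8,3,1.3,0.824,3.896,0.02
THR,Cl-,polar,0.8,3,1.3,0.521,2.683,0.02
THR,K+,polar,0.8,3,1.3,0.521,2.683,0.02
TRP,Cl-,hydrophobic,0.8,3,1.3,0.836,3.946,0.02
TRP,K+,hydrophobic,0.8,3,1.3,0.836,3.946,0.02
TYR,Cl-,polar,0.8,3,1.3,1.315,4.2,0.02
TYR,K+,polar,0.8,3,1.3,1.315,4.2,0.02
VAL,Cl-,hydrophobic,0.8,3,1.3,0.546,2.786,0.02
VAL,K+,hydrophobic,0.8,3,1.3,0.546,2.786,0.02
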