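# Mean amino-acid residue volumes (Angstrom^3) in proteins:
#   A.A. Zamyatnin (1972) "Protein volume in solution",
#   Prog. Biophys. Mol. Biol. 24, 107-123 (consensus residue volumes).
# Elemental composition is that of the residue in a polypeptide chain
# (free amino acid minus one water); electron counts follow as
# 6*C + 1*H + 7*N + 8*O + 16*S.
residue,volume,C,H,N,O,S
A,88.6,3,5,1,1,0
R,173.4,6,12,4,1,0
N,114.1,4,6,2,2,0
D,111.1,4,5,1,3,0
C,108.5,3,5,1,1,1
E,138.4,5,7,1,3,0
Q,143.8,5,8,2,2,0
G,60.1,2,3,1,1,0
H,153.2,6,7,3,1,0
I,166.7,6,11,1,1,0
L,166.7,6,11,1,1,0
K,168.6,6,12,2,1,0
M,162.9,5,9,1,1,1
F,189.9,9,9,1,1,0
P,112.7,5,7,1,1,0
S,89.0,3,5,1,2,0
T,116.1,4,7,1,2,0
W,227.8,11,10,2,1,0
Y,193.6,9,9,1,2,0
V,140.0,5,9,1,1,0
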