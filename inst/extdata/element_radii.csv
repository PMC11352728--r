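element,atomic_number,r_cov,r_vdw
H,1,0.31,1.20
He,2,0.28,1.40
Li,3,1.28,1.82
Be,4,0.96,1.53
B,5,0.84,1.92
C,6,0.76,1.70
N,7,0.71,1.55
O,8,0.66,1.52
F,9,0.57,1.47
Ne,10,0.58,1.54
Na,11,1.66,2.27
Mg,12,1.41,1.73
Al,13,1.21,1.84
Si,14,1.11,2.10
P,15,1.07,1.80
S,16,1.05,1.80
Cl,17,1.02,1.75
Ar,18,1.06,1.88
K,19,2.03,2.75
Ca,20,1.76,2.31
Ti,22,1.60,2.15
Cr,24,1.39,2.05
Mn,25,1.39,2.05
Fe,26,1.32,2.05
Co,27,1.26,2.00
Ni,28,1.24,1.97
Cu,29,1.32,1.96
Zn,30,1.22,2.01
As,33,1.19,1.85
Se,34,1.20,1.90
Br,35,1.20,1.85
Mo,42,1.54,2.10
Ru,44,1.46,2.05
Rh,45,1.42,2.00
Pd,46,1.39,2.05
Ag,47,1.45,2.10
Sn,50,1.39,2.17
Sb,51,1.39,2.06
I,53,1.39,1.98
W,74,1.62,2.10
Re,75,1.51,2.05
Os,76,1.44,2.00
Ir,77,1.41,2.00
Pt,78,1.36,2.05
Au,79,1.36,2.10
Hg,80,1.32,2.05
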