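# Default single-zeta Slater shell parameters for promolecular densities.
# One row per occupied subshell: element symbol, principal quantum number n,
# exponent zeta (bohr^-1), shell occupancy (electrons).
# H-Ar: Clementi-Raimondi effective exponents (zeta = Zeff/n) per subshell.
# K, Ca, Fe, Zn, Se, Br, I: Slater's-rules exponents with sp (and Slater d)
# groups merged; integer principal n is used in the radial power.
# Occupancies per element sum to the neutral-atom atomic number.
# The file is plain whitespace-delimited text so an alternative
# parameterisation can be dropped in (see density_model(file = ...)).
# element  n   zeta      occupancy
H    1   1.0000   1
He   1   1.6875   2
Li   1   2.6906   2
Li   2   0.6396   1
Be   1   3.6848   2
Be   2   0.9560   2
B    1   4.6795   2
B    2   1.2881   2
B    2   1.2107   1
C    1   5.6727   2
C    2   1.6083   2
C    2   1.5679   2
N    1   6.6651   2
N    2   1.9237   2
N    2   1.9170   3
O    1   7.6579   2
O    2   2.2458   2
O    2   2.2266   4
F    1   8.6501   2
F    2   2.5638   2
F    2   2.5500   5
Ne   1   9.6421   2
Ne   2   2.8792   2
Ne   2   2.8792   6
Na   1  10.6259   2
Na   2   3.2857   2
Na   2   3.4009   6
Na   3   0.8358   1
Mg   1  11.6089   2
Mg   2   3.6960   2
Mg   2   3.9129   6
Mg   3   1.1025   2
Al   1  12.5910   2
Al   2   4.1068   2
Al   2   4.4817   6
Al   3   1.3724   2
Al   3   1.3552   1
Si   1  13.5745   2
Si   2   4.5100   2
Si   2   4.9725   6
Si   3   1.6344   2
Si   3   1.4285   2
P    1  14.5578   2
P    2   4.9125   2
P    2   5.4806   6
P    3   1.8806   2
P    3   1.6288   3
S    1  15.5409   2
S    2   5.3144   2
S    2   5.9885   6
S    3   2.1223   2
S    3   1.8273   4
Cl   1  16.5239   2
Cl   2   5.7152   2
Cl   2   6.4966   6
Cl   3   2.3561   2
Cl   3   2.0387   5
Ar   1  17.5075   2
Ar   2   6.1152   2
Ar   2   7.0041   6
Ar   3   2.5856   2
Ar   3   2.2547   6
K    1  18.7000   2
K    2   7.4250   8
K    3   2.5833   8
K    4   0.5946   1
Ca   1  19.7000   2
Ca   2   7.9250   8
Ca   3   2.9167   8
Ca   4   0.7703   2
Fe   1  25.7000   2
Fe   2  10.9250   8
Fe   3   4.9167   8
Fe   3   2.0833   6
Fe   4   1.0135   2
Zn   1  29.7000   2
Zn   2  12.9250   8
Zn   3   6.2500   8
Zn   3   2.9500  10
Zn   4   1.1757   2
Se   1  33.7000   2
Se   2  14.9250   8
Se   3   7.5833   8
Se   3   4.2833  10
Se   4   1.8784   6
Br   1  34.7000   2
Br   2  15.4250   8
Br   3   7.9167   8
Br   3   4.6167  10
Br   4   2.0541   7
I    1  52.7000   2
I    2  24.4250   8
I    3  13.9167   8
I    3  10.6167  10
I    4   6.8243   8
I    4   3.7432  10
I    5   1.9000   7
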