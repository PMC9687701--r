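* nanobone default forcefield
* united-heavy-atom peptide types with polar hydroxyl hydrogens,
* hydroxyapatite mineral types (formal charges) and three-site water.
* units: kcal/mol, Angstrom, degrees, electron charges, amu

ATOMS
! type  mass    default_charge
CT    12.011   0.00
C     12.011   0.55
N     14.007  -0.40
O     15.999  -0.40
OC    15.999  -0.75
OH1   15.999  -0.66
HO     1.008   0.43
N2    14.007   0.30
N3    14.007   0.75
S     32.06   -0.20
CAL   40.078   2.00
PHO   30.974   1.00
OPH   15.999  -1.00
OHM   15.999  -1.40
HOM    1.008   0.40
OT    15.999  -0.834
HT     1.008   0.417

BONDS
! typeI typeJ  kb      r0
N    CT   320.0  1.455
CT   C    250.0  1.522
C    N    370.0  1.345
C    O    620.0  1.230
CT   CT   222.5  1.530
CT   OH1  428.0  1.420
OH1  HO   545.0  0.960
C    OC   525.0  1.260
CT   N3   263.0  1.490
CT   N2   320.0  1.460
C    N2   463.0  1.365
CT   S    214.0  1.818
OT   HT   450.0  0.9572
OHM  HOM  545.0  0.960
PHO  OPH  300.0  1.540

ANGLES
! typeI typeJ typeK  ktheta theta0 [kub rub0]
N    CT   C     70.0  111.0  8.0  2.46
X    CT   X     58.0  111.0
X    C    X     70.0  120.0
X    N    X     50.0  114.0
X    OH1  X     57.5  106.0
X    N2   X     50.0  120.0
HT   OT   HT    55.0  104.52  10.0  1.5139
X    PHO  X     98.0  109.47

DIHEDRALS
! typeI typeJ typeK typeL  kphi  n
X  CT  CT  X   0.16  3
X  C   N   X   2.50  2
X  CT  C   X   0.20  3
X  CT  N   X   0.20  3
X  CT  OH1 X   0.14  3
X  C   N2  X   2.00  2
X  CT  N3  X   0.10  3
X  CT  S   X   0.24  3

IMPROPER
! typeI typeJ typeK typeL  komega omega0
C  X  X  O    120.0  0.0
C  X  X  OC   120.0  0.0
C  X  X  N2   120.0  0.0

NONBONDED
! type  epsilon rminHalf
CT    0.0800  2.0600
C     0.1100  2.0000
N     0.2000  1.8500
O     0.1200  1.7000
OC    0.1200  1.7000
OH1   0.1521  1.7700
HO    0.0460  0.2245
N2    0.2000  1.8500
N3    0.2000  1.8500
S     0.4500  2.0000
CAL   0.1200  1.7100
PHO   0.5850  2.1500
OPH   0.1200  1.7000
OHM   0.1521  1.7700
HOM   0.0460  0.2245
OT    0.1521  1.7682
HT    0.0460  0.2245

END
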