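REMARK   synthetic stand-in for PDB entry 1KJ6 (hBD-3 mature peptide)
REMARK   residue identities: real 45-residue sequence of 1KJ6 chain A
REMARK   coordinates: SYNTHETIC idealized extended chain (CA only),
REMARK   3.8 Angstrom spacing; built offline, not downloaded
ATOM      1  CA  GLY A   1       0.000   0.000   0.000  1.00  0.00           C
ATOM      2  CA  ILE A   2       3.800   0.000   0.000  1.00  0.00           C
ATOM      3  CA  ILE A   3       7.600   0.000   0.000  1.00  0.00           C
ATOM      4  CA  ASN A   4      11.400   0.000   0.000  1.00  0.00           C
ATOM      5  CA  THR A   5      15.200   0.000   0.000  1.00  0.00           C
ATOM      6  CA  LEU A   6      19.000   0.000   0.000  1.00  0.00           C
ATOM      7  CA  GLN A   7      22.800   0.000   0.000  1.00  0.00           C
ATOM      8  CA  LYS A   8      26.600   0.000   0.000  1.00  0.00           C
ATOM      9  CA  TYR A   9      30.400   0.000   0.000  1.00  0.00           C
ATOM     10  CA  TYR A  10      34.200   0.000   0.000  1.00  0.00           C
ATOM     11  CA  CYS A  11      38.000   0.000   0.000  1.00  0.00           C
ATOM     12  CA  ARG A  12      41.800   0.000   0.000  1.00  0.00           C
ATOM     13  CA  VAL A  13      45.600   0.000   0.000  1.00  0.00           C
ATOM     14  CA  ARG A  14      49.400   0.000   0.000  1.00  0.00           C
ATOM     15  CA  GLY A  15      53.200   0.000   0.000  1.00  0.00           C
ATOM     16  CA  GLY A  16      57.000   0.000   0.000  1.00  0.00           C
ATOM     17  CA  ARG A  17      60.800   0.000   0.000  1.00  0.00           C
ATOM     18  CA  CYS A  18      64.600   0.000   0.000  1.00  0.00           C
ATOM     19  CA  ALA A  19      68.400   0.000   0.000  1.00  0.00           C
ATOM     20  CA  VAL A  20      72.200   0.000   0.000  1.00  0.00           C
ATOM     21  CA  LEU A  21      76.000   0.000   0.000  1.00  0.00           C
ATOM     22  CA  SER A  22      79.800   0.000   0.000  1.00  0.00           C
ATOM     23  CA  CYS A  23      83.600   0.000   0.000  1.00  0.00           C
ATOM     24  CA  LEU A  24      87.400   0.000   0.000  1.00  0.00           C
ATOM     25  CA  PRO A  25      91.200   0.000   0.000  1.00  0.00           C
ATOM     26  CA  LYS A  26      95.000   0.000   0.000  1.00  0.00           C
ATOM     27  CA  GLU A  27      98.800   0.000   0.000  1.00  0.00           C
ATOM     28  CA  GLU A  28     102.600   0.000   0.000  1.00  0.00           C
ATOM     29  CA  GLN A  29     106.400   0.000   0.000  1.00  0.00           C
ATOM     30  CA  ILE A  30     110.200   0.000   0.000  1.00  0.00           C
ATOM     31  CA  GLY A  31     114.000   0.000   0.000  1.00  0.00           C
ATOM     32  CA  LYS A  32     117.800   0.000   0.000  1.00  0.00           C
ATOM     33  CA  CYS A  33     121.600   0.000   0.000  1.00  0.00           C
ATOM     34  CA  SER A  34     125.400   0.000   0.000  1.00  0.00           C
ATOM     35  CA  THR A  35     129.200   0.000   0.000  1.00  0.00           C
ATOM     36  CA  ARG A  36     133.000   0.000   0.000  1.00  0.00           C
ATOM     37  CA  GLY A  37     136.800   0.000   0.000  1.00  0.00           C
ATOM     38  CA  ARG A  38     140.600   0.000   0.000  1.00  0.00           C
ATOM     39  CA  LYS A  39     144.400   0.000   0.000  1.00  0.00           C
ATOM     40  CA  CYS A  40     148.200   0.000   0.000  1.00  0.00           C
ATOM     41  CA  CYS A  41     152.000   0.000   0.000  1.00  0.00           C
ATOM     42  CA  ARG A  42     155.800   0.000   0.000  1.00  0.00           C
ATOM     43  CA  ARG A  43     159.600   0.000   0.000  1.00  0.00           C
ATOM     44  CA  LYS A  44     163.400   0.000   0.000  1.00  0.00           C
ATOM     45  CA  LYS A  45     167.200   0.000   0.000  1.00  0.00           C
TER
END
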