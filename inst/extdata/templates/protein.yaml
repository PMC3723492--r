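GLY:
- name: BB
  class: P
  charge: 0.0
  atoms:
  - 'N'
  - CA
  - C
  - O
ALA:
- name: BB
  class: P
  charge: 0.0
  atoms:
  - 'N'
  - CA
  - C
  - O
SER:
- name: BB
  class: P
  charge: 0.0
  atoms:
  - 'N'
  - CA
  - C
  - O
- name: SC1
  class: P
  charge: 0.0
  atoms:
  - CB
  - OG
  - SC1
CYS:
- name: BB
  class: P
  charge: 0.0
  atoms:
  - 'N'
  - CA
  - C
  - O
- name: SC1
  class: 'N'
  charge: 0.0
  atoms:
  - CB
  - SG
  - SC1
THR:
- name: BB
  class: P
  charge: 0.0
  atoms:
  - 'N'
  - CA
  - C
  - O
- name: SC1
  class: P
  charge: 0.0
  atoms:
  - CB
  - OG1
  - CG2
  - SC1
VAL:
- name: BB
  class: P
  charge: 0.0
  atoms:
  - 'N'
  - CA
  - C
  - O
- name: SC1
  class: C
  charge: 0.0
  atoms:
  - CB
  - CG1
  - CG2
  - SC1
LEU:
- name: BB
  class: P
  charge: 0.0
  atoms:
  - 'N'
  - CA
  - C
  - O
- name: SC1
  class: C
  charge: 0.0
  atoms:
  - CB
  - CG
  - CD1
  - CD2
  - SC1
ILE:
- name: BB
  class: P
  charge: 0.0
  atoms:
  - 'N'
  - CA
  - C
  - O
- name: SC1
  class: C
  charge: 0.0
  atoms:
  - CB
  - CG1
  - CG2
  - CD1
  - SC1
MET:
- name: BB
  class: P
  charge: 0.0
  atoms:
  - 'N'
  - CA
  - C
  - O
- name: SC1
  class: C
  charge: 0.0
  atoms:
  - CB
  - CG
  - SD
  - CE
  - SC1
PRO:
- name: BB
  class: P
  charge: 0.0
  atoms:
  - 'N'
  - CA
  - C
  - O
- name: SC1
  class: C
  charge: 0.0
  atoms:
  - CB
  - CG
  - CD
  - SC1
ASN:
- name: BB
  class: P
  charge: 0.0
  atoms:
  - 'N'
  - CA
  - C
  - O
- name: SC1
  class: P
  charge: 0.0
  atoms:
  - CB
  - CG
  - OD1
  - ND2
  - SC1
GLN:
- name: BB
  class: P
  charge: 0.0
  atoms:
  - 'N'
  - CA
  - C
  - O
- name: SC1
  class: P
  charge: 0.0
  atoms:
  - CB
  - CG
  - CD
  - OE1
  - NE2
  - SC1
ASP:
- name: BB
  class: P
  charge: 0.0
  atoms:
  - 'N'
  - CA
  - C
  - O
- name: SC1
  class: Q
  charge: -1.0
  atoms:
  - CB
  - CG
  - OD1
  - OD2
  - SC1
GLU:
- name: BB
  class: P
  charge: 0.0
  atoms:
  - 'N'
  - CA
  - C
  - O
- name: SC1
  class: Q
  charge: -1.0
  atoms:
  - CB
  - CG
  - CD
  - OE1
  - OE2
  - SC1
LYS:
- name: BB
  class: P
  charge: 0.0
  atoms:
  - 'N'
  - CA
  - C
  - O
- name: SC1
  class: Q
  charge: 1.0
  atoms:
  - CB
  - CG
  - CD
  - CE
  - NZ
  - SC1
ARG:
- name: BB
  class: P
  charge: 0.0
  atoms:
  - 'N'
  - CA
  - C
  - O
- name: SC1
  class: Q
  charge: 1.0
  atoms:
  - CB
  - CG
  - CD
  - NE
  - CZ
  - NH1
  - NH2
  - SC1
HIS:
- name: BB
  class: P
  charge: 0.0
  atoms:
  - 'N'
  - CA
  - C
  - O
- name: SC1
  class: 'N'
  charge: 0.0
  atoms:
  - CB
  - CG
  - ND1
  - CD2
  - CE1
  - NE2
  - SC1
PHE:
- name: BB
  class: P
  charge: 0.0
  atoms:
  - 'N'
  - CA
  - C
  - O
- name: SC1
  class: C
  charge: 0.0
  atoms:
  - CB
  - CG
  - CD1
  - SC1
- name: SC2
  class: C
  charge: 0.0
  atoms:
  - CD2
  - CE1
  - CE2
  - CZ
  - SC2
TYR:
- name: BB
  class: P
  charge: 0.0
  atoms:
  - 'N'
  - CA
  - C
  - O
- name: SC1
  class: C
  charge: 0.0
  atoms:
  - CB
  - CG
  - CD1
  - CD2
  - SC1
- name: SC2
  class: P
  charge: 0.0
  atoms:
  - CE1
  - CE2
  - CZ
  - OH
  - SC2
TRP:
- name: BB
  class: P
  charge: 0.0
  atoms:
  - 'N'
  - CA
  - C
  - O
- name: SC1
  class: C
  charge: 0.0
  atoms:
  - CB
  - CG
  - CD1
  - CD2
  - SC1
- name: SC2
  class: 'N'
  charge: 0.0
  atoms:
  - NE1
  - CE2
  - CE3
  - CZ2
  - CZ3
  - CH2
  - SC2
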