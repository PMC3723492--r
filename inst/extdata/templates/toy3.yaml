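residue: TOY
beads:
- name: HD
  class: P
  charge: 0.0
  atoms:
  - HD
  mass: 72.0
  phosphate: yes
- name: TL1
  class: C
  charge: 0.0
  atoms:
  - TL1
  mass: 72.0
- name: TL2
  class: C
  charge: 0.0
  atoms:
  - TL2
  mass: 72.0
bonds:
- - 1.0
  - 2.0
- - 2.0
  - 3.0
bond_r0: 4.7
bond_k: 25.0
angles:
- - 1.0
  - 2.0
  - 3.0
angle_theta0: 180.0
angle_k: 25.0
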