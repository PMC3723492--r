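residue: POPC
beads:
- name: NC3
  class: Q
  charge: 1.0
  atoms:
  - 'N'
  - C11
  - C12
  - C13
  - C14
  - C15
  - NC3
- name: PO4
  class: Q
  charge: -1.0
  atoms:
  - P
  - O11
  - O12
  - O13
  - O14
  - PO4
  phosphate: yes
- name: GL1
  class: 'N'
  charge: 0.0
  atoms:
  - C1
  - C2
  - O21
  - C21
  - O22
  - GL1
- name: GL2
  class: 'N'
  charge: 0.0
  atoms:
  - C3
  - O31
  - C31
  - O32
  - GL2
- name: C1A
  class: C
  charge: 0.0
  atoms:
  - C22
  - C23
  - C24
  - C25
  - C1A
- name: C2A
  class: C
  charge: 0.0
  atoms:
  - C26
  - C27
  - C28
  - C29
  - C2A
- name: C3A
  class: C
  charge: 0.0
  atoms:
  - C210
  - C211
  - C212
  - C213
  - C3A
- name: C4A
  class: C
  charge: 0.0
  atoms:
  - C214
  - C215
  - C216
  - C217
  - C218
  - C4A
- name: C1B
  class: C
  charge: 0.0
  atoms:
  - C32
  - C33
  - C34
  - C35
  - C1B
- name: C2B
  class: C
  charge: 0.0
  atoms:
  - C36
  - C37
  - C38
  - C39
  - C2B
- name: C3B
  class: C
  charge: 0.0
  atoms:
  - C310
  - C311
  - C312
  - C3B
- name: C4B
  class: C
  charge: 0.0
  atoms:
  - C313
  - C314
  - C315
  - C4B
- name: C5B
  class: C
  charge: 0.0
  atoms:
  - C316
  - C317
  - C318
  - C5B
bonds:
- - 1.0
  - 2.0
- - 2.0
  - 3.0
- - 3.0
  - 4.0
- - 3.0
  - 5.0
- - 5.0
  - 6.0
- - 6.0
  - 7.0
- - 7.0
  - 8.0
- - 4.0
  - 9.0
- - 9.0
  - 10.0
- - 10.0
  - 11.0
- - 11.0
  - 12.0
- - 12.0
  - 13.0
bond_r0: 4.7
bond_k: 25.0
angles:
- - 3.0
  - 5.0
  - 6.0
- - 5.0
  - 6.0
  - 7.0
- - 6.0
  - 7.0
  - 8.0
- - 4.0
  - 9.0
  - 10.0
- - 9.0
  - 10.0
  - 11.0
- - 10.0
  - 11.0
  - 12.0
- - 11.0
  - 12.0
  - 13.0
angle_theta0: 180.0
angle_k: 25.0
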