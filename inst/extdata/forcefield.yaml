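classes:
- P
- 'N'
- C
- Q
epsilon:
  P:
    P: 5.0
    'N': 4.0
    C: 2.0
    Q: 5.0
  'N':
    'N': 3.5
    C: 3.0
    Q: 4.0
  C:
    C: 3.5
    Q: 2.0
  Q:
    Q: 4.5
sigma: 4.7
eps_r: 15.0
lj_window:
- 9.0
- 12.0
coul_window:
- 0.0
- 12.0
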