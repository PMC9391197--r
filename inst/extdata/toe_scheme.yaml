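n_fixed: 19
anchor_tol: 0.02
curves:
- from: 1
  to: 3
  n_raw: 10
  role: toe_outline
- from: 3
  to: 5
  n_raw: 10
  role: toe_outline
- from: 5
  to: 7
  n_raw: 10
  role: toe_outline
- from: 7
  to: 9
  n_raw: 10
  role: toe_outline
- from: 9
  to: 8
  n_raw: 10
  role: toe_outline
- from: 8
  to: 6
  n_raw: 10
  role: toe_outline
- from: 6
  to: 4
  n_raw: 10
  role: toe_outline
- from: 4
  to: 2
  n_raw: 10
  role: toe_outline
- from: 10
  to: 11
  n_raw: 10
  role: lamella_edge
- from: 12
  to: 13
  n_raw: 10
  role: lamella_edge
- from: 14
  to: 15
  n_raw: 10
  role: lamella_edge
- from: 16
  to: 17
  n_raw: 10
  role: lamella_edge
- from: 18
  to: 19
  n_raw: 10
  role: lamella_edge
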