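name: LPN3B
states:
- S1
- S2
- S3
- S4
controls:
- e1
- e2
- e3
params:
  k1: 1.0
  k2: 1.0
  k3: 1.0
rhs:
  S1: '0'
  S2: k1 * S1 * e1 - k2 * S2 * e2
  S3: k2 * S2 * e2 - k3 * S3 * e3
  S4: k3 * S3 * e3
x0:
- 1.0
- 0.0
- 0.0
- 0.0
horizon:
  t0: 0.0
  tf_mode: free
  tf_bounds:
  - 0.5
  - 10.0
objectives:
- mayer: tf
  sense: min
  name: transition_time
- lagrange: S2 + S3
  sense: min
  name: intermediate_accumulation
path_constraints:
- expr: e1 + e2 + e3
  bound: 1.0
  dir: <=
  label: enzyme_capacity
point_constraints:
- expr: S4
  time: tf
  bound: 0.9
  rel: ==
  label: product_target
control_bounds:
  lower:
  - 0.0
  - 0.0
  - 0.0
  upper:
  - 1.0
  - 1.0
  - 1.0
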