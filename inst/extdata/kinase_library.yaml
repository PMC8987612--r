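# Minimal kinase consensus-motif library.
# Offsets are relative to the phosphosite (negative = N-terminal side);
# center lists the allowed phosphoacceptor residues.
PKA:
  center: [S, T]
  constraints:
    "-3": [R]
    "-2": [R]
CDK:
  center: [S, T]
  constraints:
    "1": [P]
CDK_strict:
  center: [S, T]
  constraints:
    "1": [P]
    "3": [K, R]
MAPK:
  center: [S, T]
  constraints:
    "-2": [P]
    "1": [P]
CK2:
  center: [S, T]
  constraints:
    "3": [D, E]
MK2:
  center: [S, T]
  constraints:
    "-5": [L, I, V, F, M]
    "-3": [R]
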