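# Default mirdiag pipeline configuration.
# Motifs are placeholder seed-region heptamers: replace them with your own
# motif hypotheses; the descriptor contract only requires RNA strings.
seed: 1
k: 5
classifier:
  kind: bayesnet
  alpha: 0.5
sequence:
  include_dinucleotides: true
  motifs:
    - AGCUUAU
    - AAGUGCU
    - UAAGGCA
    - ACUGCAU
    - UUGGUCC
    - AGCAGCA
    - UUCAAGU
    - AAAGUGC
  mw_constants:
    A: 329.2
    C: 305.2
    G: 345.2
    U: 306.2
  mw_terminal: 18.0
annotation:
  score_threshold: 80
selection:
  min_gain: 0
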