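# Terminal-fusion screen: 2 fusion termini x 6 GGS linker lengths crossed
# with 11 spacings x 2 orientations + the unflanked site (23 target sites).
# All sequences are synthetic placeholders with the published geometry.
lox:
  name: loxSYN
  left_half: ATAACTTCGTATA
  spacer: GCATACAT
  right_half: TATACGAAGTTAT
motif:
  name: zifSYN
  sequence: GCGTGGGCG
spacings: [0, 1, 2, 3, 4, 5, 6, 7, 8, 9, 10]
orientations: [A, B]
include_unflanked: true
mode: TERMINAL
modes: [N_TERMINAL, C_TERMINAL]
linker_grid: [2, 4, 6, 8, 10, 12]
thresholds:
  min_phred: 10
  min_margin: 8
  p_threshold: 0.001
  distance_range: [4, 6]
seed: 1
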