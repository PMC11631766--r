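# Insertional-fusion screen: 8 x 8 left/right GGS linker pairs at junction
# 278/279, crossed with the same 23 target sites (1,472 combinations).
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
mode: INSERTIONAL
linker_left_grid: [1, 2, 3, 4, 5, 6, 7, 8]
linker_right_grid: [1, 2, 3, 4, 5, 6, 7, 8]
insertion_junction: 278
thresholds:
  min_phred: 10
  min_margin: 8
seed: 1
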