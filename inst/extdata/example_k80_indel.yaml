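# Example run: 120 nucleotide sites under K80 (kappa = 2) with discrete-gamma
# rate variation, a fast-field deletion process and a geometric insertion
# process, along a five-taxon tree.
seed: 7
tree: "(((human:0.1,chimp:0.12):0.08,macaque:0.2):0.1,(mouse:0.3,rat:0.28):0.15);"
root:
  length: 120
processes:
  k80:
    type: k80
    kappa: 2
  del:
    type: deletion
    rate: 0.05
    mode: fast_field
    lengths: {kind: user_table, lengths: [1, 2, 3], probs: [0.6, 0.3, 0.1]}
  ins:
    type: insertion
    rate: 0.03
    template: k80
    lengths: {kind: geometric, p: 0.5}
partitions:
  - name: all
    from: 1
    to: 120
    processes: [k80, del, ins]
    site_rates: {kind: discrete_gamma, alpha: 0.8, categories: 4}
    deletion_tolerance: 0.7
outputs:
  include_internal: false
  drop_all_gap_columns: true
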