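# Demo study conditions: shared 3 x 1 Mb reference genome, generations
# G0/G1/G3 at telomere scale 1/0.6/0.3, matched KO and input per generation.
genome:
  n_chrom: 3
  chrom_length: 1000000
  telomere_units: 800
  subtelomere_len: 25000
conditions:
  telomere_scales: {G0: 1.0, G1: 0.6, G3: 0.3}
  n_subtelomeric: 25
  n_interstitial: {G0: 15, G1: 215, G3: 575}
  gradient_decay: 1.0e-5
site:
  width: 200
  occupancy: [2, 8]
depth: 100000
read_length: 50
error_rate: 0
bin_size: 200
p_cutoff: 1.0e-3
pseudocount: 0.5
merge_gap_bins: 1
n_profile_bins: 20
seed: 1
use_truth_alignments: false
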