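{
  "v_segments": [
    {"name": "TRBV-A", "seq": "TGTGCCAGCAGCTTG", "prob": [0.20]},
    {"name": "TRBV-B", "seq": "TGTGCCAGCAGCGAA", "prob": [0.17]},
    {"name": "TRBV-C", "seq": "TGCAGTGCTAGAGAT", "prob": [0.15]},
    {"name": "TRBV-D", "seq": "TGTGCCTGGAGTGTC", "prob": [0.13]},
    {"name": "TRBV-E", "seq": "TGTGCTTCCAGGACA", "prob": [0.11]},
    {"name": "TRBV-F", "seq": "TGCAGCGTTGAGGAC", "prob": [0.09]},
    {"name": "TRBV-G", "seq": "TGTGCCACCAGCCGG", "prob": [0.08]},
    {"name": "TRBV-H", "seq": "TGTGCATCGGGGCTG", "prob": [0.07]}
  ],
  "j_segments": [
    {"name": "TRBJ-a", "seq": "ACTGAAGCTTTCTTT", "prob": [0.25]},
    {"name": "TRBJ-b", "seq": "TACGAGCAGTACTTC", "prob": [0.20]},
    {"name": "TRBJ-c", "seq": "GGGACCCAGTACTTT", "prob": [0.17]},
    {"name": "TRBJ-d", "seq": "AATGAGCAGTTCTTT", "prob": [0.15]},
    {"name": "TRBJ-e", "seq": "GAGACCCAGTATTTT", "prob": [0.13]},
    {"name": "TRBJ-f", "seq": "GGGGAACTGTTTTTT", "prob": [0.10]}
  ],
  "v_del_pmf": [0.35, 0.25, 0.20, 0.12, 0.08],
  "j_del_pmf": [0.35, 0.25, 0.20, 0.12, 0.08],
  "ins_len_pmf": [0.05, 0.08, 0.12, 0.14, 0.15, 0.13, 0.11, 0.09, 0.06, 0.04, 0.03],
  "ins_nt_probs": {"A": [0.22], "C": [0.26], "G": [0.30], "T": [0.22]}
}
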