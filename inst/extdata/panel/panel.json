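{
  "coi_reference_fasta": "coi_reference_synthetic.fasta",
  "spacer_fasta": "spacer_exemplars_synthetic.fasta",
  "coi_diagnostic_position": 300,
  "coi_diagnostic_note": "Fragment coordinate of the diagnostic C/T site; maps to position 2382 in mitogenome reference numbering. C = African, T = European.",
  "restriction_motif": "AGATCT",
  "cut_offset": 1,
  "min_visible_bp": 50,
  "synthetic": true
}
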