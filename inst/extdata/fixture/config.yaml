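precursors: precursors.tsv
stacks: stacks.tsv
sample_sheet: sample_sheet.tsv
known_matures: known_matures.fasta
family_prefix: Jcu
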