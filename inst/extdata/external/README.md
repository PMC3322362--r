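# External benchmark inputs (not distributed)

The structure-derived benchmark pair lists are distributed as
supplementary data of the original study, not with this package. To run
the benchmark-loader checks, place here:

- `RPI2241_pairs.tsv` — 2241 positive RNA-protein pairs (two tab-separated
  columns: protein sequence, RNA sequence)
- `RPI369_pairs.tsv` — the 369-pair non-ribosomal subset, same format

Both load with `read_pairs(path, dialect = "seq_pairs")`.
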