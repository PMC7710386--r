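# External data drop-in

`datafileS1.tsv` (not shipped): the full fish pattern survey annotation
table — one row per species, columns `species`, `genus`, `family`,
`order` and the 11 binary motif flags `St-H`, `St-D`, `St-V`, `Maze`,
`Sp-D`, `Sp-L`, `Eyes`, `Area`, `Sddl`, `Bltc`, `Mono` (see
`?read_annotations`). Placing it here (or pointing the `PATTERNBLEND_S1`
environment variable at it) enables the acceptance test that reproduces
the published genus-level Maze-spot collocation values.
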