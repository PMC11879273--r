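# extdata

Place the study's supplementary data under `study/` to enable the
data-reproduction acceptance tests (or point
`options(norppa.study_data_dir = ...)` anywhere else):

- `study/file_s1_alignment.fasta`, `study/file_s1_popmap.tsv` — the 246
  aligned mitogenome coding regions (10,713 bp) with an `id<TAB>population`
  map over the areas Atlantic Arctic / Baltic Sea / Lake Ladoga /
  Lake Saimaa.
- `study/file_s3_landmarks.csv` — 180 specimens in wide format
  (`specimen,group,sex,x1,y1,z1,...,x31,y31,z31`), groups High Arctic /
  East Greenland / Baltic Sea / Lake Ladoga / Lake Saimaa.
- `study/file_s3_pairing.tsv` — bilateral landmark pairing
  (`left<TAB>right` rows, midline landmarks as single-column rows,
  1-based).

No data files ship with the package; synthetic inputs with known truth
are generated by `analysis/01_simulate_data.R` and the `simulate_*`
functions.
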