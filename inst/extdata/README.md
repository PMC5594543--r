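# Packaged fixture tables (synthetic)

All three files are generated by `build_network_fixture(seed = 1)` and are
entirely synthetic: they mirror the *structure* of real database exports,
not any real database content.

To run the network stage on real data, export your own tables with these
columns (tab-separated, header row):

- `synthetic_target_predictions.tsv` — one row per (miRNA, gene, algorithm)
  prediction, columns `mirna`, `gene`, `algorithm`. Algorithm names must
  come from the six-member set returned by `prediction_algorithms()`
  (DIANA-microTv4.0, miRanda-rel2010, PicTar2, PITA, RNA22v2,
  Targetscan6.2), the consensus universe used for bona fide target
  calling. A miRWalk-style export maps directly: one indicator column per
  algorithm becomes one row per supporting algorithm.
- `synthetic_disease_genes.tsv` — one row per (disease, gene) association,
  columns `disease`, `gene`, `curated` (logical). Only curated rows are
  used, and only diseases with at least 20 curated genes are kept. A
  DisGeNET-style export maps `diseaseName` -> `disease`, `geneSymbol` ->
  `gene`, and its curated-source flag -> `curated`.
- `synthetic_coagulation_genes.txt` — one gene symbol per line (a
  KEGG-style pathway member list).
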