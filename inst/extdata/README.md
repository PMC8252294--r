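# extdata

Optional user-supplied inputs for the real-data replication check in
`tests/testthat/test-acceptance.R` (none ship with the package):

* `published_metabolite_table.csv` — long replicate-level normalised
  peak areas with columns `accession`, `replicate`, `feature_id`,
  `class_metabolite` (`acylsugar`/`volatile`), `abundance`.
* `published_phenotypes.csv` — columns `accession`, `insect`
  (`whitefly`/`thrips`), `class` (`resistant`/`susceptible`).
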