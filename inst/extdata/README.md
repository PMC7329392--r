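# extdata

Optional real-data fixtures consumed by the convention-check test
(`tests/testthat/test-acceptance.R`, Ccg-4 block) and by
`kep_fragment_report()`:

* `ccg4_homologs.fasta` — the two published pheromone-precursor records
  EAA35858.1 (*Neurospora crassa* Ccg-4) and PQE12560.1 (*Rutstroemia*
  sp. homolog), fetched from NCBI protein.  Not redistributed here.
* `ccg4_signalp.txt` — SignalP 4.1 short-format predictions for the two
  records (optional; the built-in heuristic is used when absent).

With these files in place the test verifies the Kex2 splitting
convention against the published fragment counts (12 and 15 fragments;
2 and 3 Y-containing fragments of 38/40 and 13/16/22 residues).
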