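Histone-fold worked example inputs (not redistributed with the package).

To run the worked example and its acceptance tests, place here:

  4uuz.pdb   https://files.rcsb.org/download/4UUZ.pdb
  1p3m.pdb   https://files.rcsb.org/download/1P3M.pdb
  6m4g.pdb   https://files.rcsb.org/download/6M4G.pdb

and a FASTA file `sequences.fasta` of the author-deposited sequences with
headers renamed to ENTRYID_CHAIN, e.g.

  >4uuz_A
  ...
  >1p3m_A
  ...
  >6m4g_C
  ...

(the deposited records are available from the RCSB PDB entry pages, e.g.
https://www.rcsb.org/fasta/entry/4UUZ). Then:

  library(strucphylo)
  worked_example(system.file("extdata", "worked_example",
                             package = "strucphylo"))
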