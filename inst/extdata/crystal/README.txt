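Deposited crystal structures of N-SH2/phosphopeptide complexes are not
redistributable inside this package. To enable the acceptance check that
recomputes the published pocket distances, place the PDB-format entries
here as <ID>.pdb (IDs: 1AYA, 1AYB, 3TL0, 4QSY, 5DF6, 5X7B, 5X94), e.g.

    curl -O https://files.rcsb.org/download/1AYB.pdb

The corresponding test in tests/testthat/test-acceptance.R reports as
failed while these files are absent.
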