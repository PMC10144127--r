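# extdata

No coordinate data ships with the package: all validation structures are
generated in code (`make_barrel()`, `make_archetype()`), and experimental
models cannot be redistributed here.

To run the experimental validation in the test suite, download the hVDAC1
NMR entry 2K4T from the PDB and place it in this directory as `2k4t.pdb`
before installing:

    curl -o inst/extdata/2k4t.pdb https://files.rcsb.org/download/2K4T.pdb

The corresponding acceptance test analyzes model 1 of that entry (19
strands, Class I, ellipticity near 0.9, H-bonded terminal strands ~4.7 A
apart) and fails when the file is absent.
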