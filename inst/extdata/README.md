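# External data drop-in

Place a local copy of the original study's supplementary spectral /
weighted-centroid CSV files (extracted) under `supplementary/` here to
let the test suite and `svm_benchmark()` re-score the published
classification benchmarks on the real data.  No public accession
exists from which these files could be fetched automatically; the
readers (`read_centroids_csv()`, `read_spectrum_csv()`) sniff common
header variants, so the files can be used as extracted.

Everything else the package needs is generated in code.
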