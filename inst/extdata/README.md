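# External inputs (optional)

Two acceptance tests run against the published nine-strain dataset and
look for externally supplied inputs here:

- `LZYI01/LZYI01.fasta` — the deposited whole-genome-shotgun draft
  assembly of strain ZBY (accession LZYI01000000), used to check the
  assembly statistics (total bases, contig count, N50, N90, GC) against
  the published values.
- `real9/hits.m8` and `real9/genes.tsv` — the all-vs-all protein hit
  table (12-column tabular format) and gene table of the nine strains,
  used to check that the fitted Heaps exponent calls the pan-genome
  closed.

Neither file ships with the package (the assembly alone is ~3.8 Mb and
the hit table requires an all-vs-all protein search); without them the
two tests fail with a pointer to this directory. Every other test is
self-contained.
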