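Package: grnadesign
Title: CRISPR/Cas9 Guide RNA Design with Genome-Wide Off-Target Counting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Selects CRISPR/Cas9 guide RNA (gRNA) target sites from an input
    sequence with minimized off-target potential. Enumerates 20-nt
    protospacers adjacent to a protospacer adjacent motif (PAM, e.g. NGG) on
    both strands, annotates each candidate with GC content,
    nearest-neighbor melting temperature and a pol III terminator (TTTT)
    flag, counts genome-wide perfect matches of the full target and of its
    12-mer and 8-mer seed sequences adjacent to the PAM via an in-process
    k-mer index, performs mismatch- and gap-tolerant off-target searches
    with visualized alignments, and exports results as tab-delimited text
    or JSON. Includes a seeded synthetic-genome generator that plants
    ground-truth on- and off-target sites for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    stringi,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
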