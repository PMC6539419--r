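Package: metranet
Title: Metabolome-Transcriptome Association Analysis for Staged Omics Designs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Differential-metabolite calling by fold change and PLS-DA variable
    importance in projection (VIP), pathway over-representation analysis with
    Benjamini-Hochberg false-discovery control, nine-quadrant gene-metabolite
    association, and signed bipartite transcript-metabolite correlation
    networks, for multi-stage designs with replicated samples such as the
    NEC/PEC/GE stages of cotton somatic embryogenesis. Includes a synthetic
    data generator with planted differential features, enriched pathways and
    correlated gene-metabolite pairs for end-to-end validation, plus curated
    reference tables of classic somatic-embryogenesis gene-metabolite pairs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    yaml
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
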