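Package: cycadrisk
Title: Phylogeny-Aware Extinction Risk and Diversity Hotspot Analysis for Cycads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for asking how an ongoing extinction crisis would prune a
    clade's tree of life, built around the cycads, the most threatened major
    plant group. Computes fair-proportion evolutionary distinctiveness (ED)
    and EDGE conservation priority scores, Faith's phylogenetic diversity
    (PD) remaining under scenario-based species losses against random-pruning
    null distributions, the Fritz-Purvis D statistic for phylogenetic signal
    in binary threat status, maximum-likelihood diversification model fitting
    and selection on branching times (pure-birth, birth-death,
    density-dependent, and multi-rate Yule models), and grid-based diversity
    mapping (species richness, PD, weighted and phylogenetic endemism, mean
    EDGE) with percentile hotspot extraction and protected-area gap analysis.
    Includes a synthetic-data generator that emulates the cycad tree of
    life's distinctive topology (old monophyletic genera with long stems and
    recent crown radiations), IUCN threat-category marginals, right-skewed
    gridded range sizes, and patchy protected-area masks, so the whole
    pipeline is testable end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape (>= 5.0),
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    picante,
    withr
Config/testthat/edition: 3
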