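Package: mlsupertree
Title: Approximate Maximum Likelihood Supertree Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates maximum likelihood supertrees from sets of partially
    overlapping phylogenetic trees under the Steel-Rodrigo exponential model:
    the probability of observing an input tree given a candidate supertree
    decays exponentially with the Robinson-Foulds distance between the input
    tree and the supertree pruned to the input tree's taxa. Provides canonical
    split encoding and Robinson-Foulds distances, per-input-tree and total
    log-likelihood scoring, stepwise-addition starting trees, four SPR-based
    hill-climbing search strategies, an exhaustive search for small taxon
    sets, bootstrap resampling of tree sets with majority-rule consensus
    support, a winning-sites (sign) test for competing supertree hypotheses,
    CONSEL-compatible export of input-tree-wise log-likelihoods, tree-file
    utilities (pruning, derooting, rerooting, polytomy resolution, newick and
    nexus conversion), and a synthetic gene-tree generator matching the
    model's assumed error process.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape (>= 5.0),
    phangorn,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
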