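Package: ltmcascade
Title: Computational Cascades and Emergent Boolean Logic in Threshold Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates linear threshold model (LTM) cascades and their
    antagonistic (inhibitory) variant on Erdos-Renyi random graphs, and
    identifies the Boolean function each network node computes on binary
    perturbations of designated seed nodes. Provides percolation theory for
    the giant connected component, decision-tree complexity of Boolean
    functions via Hamming-cube axis symmetries, a catalog of minimal logic
    motifs realising every two-input function, complexity-based predictions
    of function frequencies, and ensemble experiment drivers for
    rank-ordering statistics and the antagonism / connectivity diversity
    surface. Includes a command-line interface for reproducible simulation
    runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    Rcpp,
    stats,
    utils,
    tools,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
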