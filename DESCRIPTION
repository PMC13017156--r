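Package: bnsbm
Title: Bipartite Noisy Stochastic Block Models for Structured Multiple Testing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simultaneous inference for matrices of association z-scores,
    such as microbe-metabolite differential-correlation statistics. The
    constellation of null and alternative hypotheses is modelled as a latent
    bipartite stochastic block model whose edges are observed only through a
    two-component mixture of null and alternative densities. A variational
    EM algorithm estimates mixing proportions, block connectivities and
    per-block alternative densities; the number of row and column blocks is
    chosen by an integrated classification likelihood (ICL) criterion.
    Structured l-values (posterior null probabilities given the latent
    graph) are thresholded to control the marginal false discovery rate
    while pooling information within blocks for higher power. Includes
    simulators for modular, nested and preferential-attachment bipartite
    graphs, Benjamini-Hochberg and q-value baselines, and a pipeline to
    build differential cross-correlation z-scores from paired omics tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    mclust,
    optparse,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
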