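Package: riverphylo
Title: Riverine Barrier Hypothesis Assessment from Dated Phylogenies
Version: 0.1.0
Authors@R: person("riverphylo", "maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: Tools to test the riverine barrier hypothesis from phylogenies of
    georeferenced samples. Delimits evolutionary lineages on a maximum-likelihood
    tree under single-rate and multi-rate Poisson Tree Processes models, assigns
    samples to river banks from oriented river polylines, classifies
    between-lineage divergences as spatially congruent with a river barrier,
    extracts node-age posteriors from dated tree samples, computes 95% highest
    posterior density intervals, groups synchronous divergences, and tests
    divergence timing against geological river-formation ages. Includes seeded
    synthetic-data generators (two-regime branch-length trees with known
    delimitation, planted river geography, pseudo-posterior tree sets) so the
    whole pipeline is testable against planted truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape (>= 5.0),
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
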