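Package: poregate
Title: Hydrophobic Gating Analysis of Ion Channel Pores from Molecular Dynamics Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies wetting and dewetting of hydrophobic constrictions in
    ion channel pores from molecular dynamics trajectories. Provides slab
    water-occupancy time series, occupancy histograms and mean-occupancy
    comparisons between wild-type and mutant channels, bulk-normalized 3D
    water density grids (OpenDX export), HOLE-style maximal-sphere pore
    radius profiles with threshold classification, and 1D potential-of-mean-
    force reconstruction from harmonically biased umbrella-sampling windows
    via the weighted histogram analysis method (WHAM). A synthetic-data
    module generates pseudo-atomic pore structures, two-state (telegraph)
    wetting trajectories and umbrella-window samples with analytically known
    ground truth, so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
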