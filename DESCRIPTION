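Package: unfoldscape
Title: Free-Energy Landscapes and Transition-State Analysis for Protein
    Unfolding Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing protein unfolding from coordinate
    trajectories: pairwise C-alpha RMSD matrices reduced by classical
    multidimensional scaling into an RMSD-space step-vector representation,
    statistical free-energy landscapes from step-vector terminal populations
    (deltaF = -RT log(P/P0)), reaction-coordinate extraction with activation
    barrier, channel-index and intermediate-well statistics, transition-state
    theory unfolding rates, native-contact and radius-of-gyration series with
    molten-globule classification in the native-versus-total contact plane,
    transition-ensemble demarcation, and contact-ratio phi-values for mutant
    ensembles. Includes a synthetic-data module generating Brownian samples on
    analytic free-energy surfaces and toy-protein unfolding trajectories with
    known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    bio3d,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'contacts.R'
    'io.R'
    'landscape.R'
    'methods.R'
    'phi.R'
    'synthetic-protein.R'
    'rmsd-space.R'
    'pipeline.R'
    'plots.R'
    'synthetic-potentials.R'
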