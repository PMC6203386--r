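Package: petnorm
Title: Template-Based Spatial Normalization and SRTM Quantification for
    Small-Animal Brain PET
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying striatal radioligand binding in mouse
    brain PET studies under different spatial-normalization strategies.
    Provides NIfTI-1 volume handling with dynamic frame schedules, rigid
    (downhill-simplex, mutual-information) and low-frequency cosine-basis
    non-linear registration, construction of MRI, tracer-PET and CT
    templates in a shared standardized space, three normalization routes
    (MRI-, PET- and CT-template based), simplified reference tissue model
    (SRTM) fitting of binding potential with a cerebellar reference, a
    multimodal digital mouse-brain phantom generator with striatal atrophy
    and genotype effects, and the agreement and effect-size statistics
    (Cohen's d, Bland-Altman limits of agreement, Pearson correlation)
    used to compare the normalization routes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'geometry.R'
    'imaging_core.R'
    'kinetics.R'
    'petnorm-package.R'
    'transforms.R'
    'registration.R'
    'phantom.R'
    'templates.R'
    'routes.R'
    'stats.R'
    'pipeline.R'
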