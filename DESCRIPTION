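Package: flowpulse
Title: Cerebral Arterial Pulsatility Metrics from 4D Flow MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies cerebral arterial pulsatility from time-resolved
    phase-contrast (4D flow) MRI flow waveforms. Computes Gosling's
    pulsatility index (PI) and flow volume pulsatility (FVP, the cyclic
    volume expansion of the downstream arterial tree) with R-R interval
    standardization, bilateral averaging with contralateral fallback, and
    total cerebral blood flow. Includes a voxelized pulsatile Poiseuille
    vessel phantom with retrospectively gated 20-phase reconstruction and
    centerline flow extraction for validating the metrics end to end, a
    synthetic stroke-cohort generator with gamma-distributed white matter
    hyperintensity burden, brain volumes and cognitive outcomes, and the
    multivariable association analysis (gamma/log and Gaussian/identity
    generalized linear models, small vessel disease subgroup, ICC(2,1)
    interrater agreement).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
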