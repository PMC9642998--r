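Package: sanpop
Title: Population-of-Models Analysis of Sinoatrial Node Dysfunction and Cardiac Rhythm Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for studying sick-sinus-syndrome-like phenotypes with a
    population-of-models approach. Provides a mouse sinoatrial-node pacemaker
    myocyte ODE model with isoproterenol and carbachol condition transforms,
    log-normal parameter-population generation, physiological filtering,
    phenotype classification and rank-sum parameter screening; beat-series
    rhythm analytics (sinus-arrest and atrioventricular-block episode calling,
    sinus-node recovery time, cycle-length variation, R-peak detection); the
    incidence, chi-square, summary t-test and boxplot-notch statistics used for
    electrocardiographic screening tables; and synthetic generators (beat
    trains, stylized ECG waveforms, an analytic surrogate pacemaker population)
    with machine-readable ground truth for pipeline validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    signal,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
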