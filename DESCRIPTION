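Package: cochsim
Title: Simulation of Normal and Electric Hearing at the Auditory Nerve
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates the auditory periphery for normal (acoustic) and
    electric (cochlear implant) hearing. Provides an ERB-spaced rounded
    exponential cochlear filterbank with sigmoidal rate-level functions and
    binomial spike sampling; four cochlear implant sound coding strategies
    (CIS, ACE, FSP and a simplified HiRes120 current-steering scheme)
    producing electrodograms; an electrode-nerve interface with exponential
    spatial spread of current, a two-Gaussian nerve impulse response and an
    electrical rate-level stage; current level fitting by across-stimulus
    nervegram variance maximization; and psychophysical analysis procedures
    (intensity discrimination with a trained linear classifier, psychometric
    threshold and Weber fraction computation, electrodogram interaural time
    and level difference measurement, cue bias weights, localization grids)
    together with a noise vocoder and synthetic stimulus generators.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, signal, jsonlite
Suggests: testthat (>= 3.0.0), withr, yaml, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
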