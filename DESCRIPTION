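Package: speechABR
Title: Simulation and Analysis of Speech-Evoked Auditory Brainstem Responses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for simulating and analysing auditory brainstem responses
    evoked by a short consonant-vowel token (speech-ABR). Provides a Klatt-style
    synthesiser for a 40 ms five-formant [da] stimulus, an epoch-level simulator
    of aided/unaided recordings in quiet and in background noise with known
    ground truth, alternating-polarity averaging with artifact rejection and
    zero-phase filtering, bootstrap noise-floor confidence bands with
    two-criterion peak detection (waves V, A, D, E, F, O), and fundamental
    frequency (F0) encoding analysis via empirical mode decomposition of the
    stimulus fundamental waveform, complex cross-correlation with its Hilbert
    transform, and a one-sample Hotelling T-squared presence test on segmented
    responses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
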