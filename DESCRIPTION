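Package: hybridbrain
Title: Hybrid Task-Network and Connectome Simulation of Visual Working Memory
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Embeds a task-performing large-scale neural model (LSNM) of
    visual delayed match-to-sample working memory into a whole-brain
    Wilson-Cowan connectome simulation. Provides connectome loading and
    synthesis, stereotaxic placement of 81-unit task modules at host nodes,
    stochastic Euler integration of the coupled hybrid network with
    conduction delays, integrated synaptic activity, a Balloon-Windkessel
    BOLD forward model, task scoring, and within-condition functional
    connectivity analyses with Fisher-Z group averaging and paired t tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    yaml
Suggests:
    deSolve,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
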