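Package: tokenaccrual
Title: Incentive Design for Token-Rewarded Participant Recruitment
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Models participant recruitment on a token-incentivized health
    platform as a daily consent process with reward-dependent consent
    probabilities. Provides synthetic participant-pool generation for two
    scenarios (a life-insurance vitality/life-log program and an anticancer
    clinical-trial recruitment), closed-form expected enrollment by day,
    minimal expected recruitment time, a Monte Carlo daily-round simulator,
    grid optimization of the recruiter's cost (reward outlay plus
    time-weighted duration), elasticity-style sensitivity analysis, and a
    simulation-versus-optimization comparison report. Includes configuration
    parsing and a command-line experiment runner with reproducible seeded
    output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
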