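Package: pestdyn
Title: Seasonal Competition and Host-Parasitoid Dynamics of Maize Stemborers
    and Fall Armyworm
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Stock-and-flow simulator for the population dynamics of three
    maize stemborers (Busseola fusca, Sesamia calamistis, Chilo partellus)
    and the fall armyworm (Spodoptera frugiperda) competing for a seasonal
    maize resource in Kenya, each pest coupled to a lumped parasitoid guild.
    Pest growth follows Lotka-Volterra interspecific competition with a
    season-switching carrying capacity (two 3-month cropping windows per
    year plus a wild refuge), delayed pest entry and parasitism onset, and a
    between-season carryover. Includes scenario builders for all single- and
    multi-species systems, estimation of competition coefficients from
    density-dependent larval-survival experiments by intercept-free multiple
    regression, trajectory metrics (dominance shares, peaks, cross-system
    ratios, host-parasitoid cycle detection, phase portraits), synthetic
    data generators, and CSV/JSON input-output with a deterministic scenario
    gallery.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
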