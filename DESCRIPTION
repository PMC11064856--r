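Package: vermivory
Title: Diet Composition, Earthworm Bioenergetics and Home-Range Prediction
    for a Vermivorous Bird
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing parental feeding-visit records of
    earthworm-specialist (vermivorous) birds and extrapolating them to
    whole-breeding-event energy budgets. Provides typed readers and
    validators for prey-item level feeding-visit tables, a seeded synthetic
    data generator emulating the statistical structure of nest-observation
    data, diet composition and prey-length summaries with per-nest Fisher
    exact tests combined by Fisher's method, an allometric length to
    ash-free-dry-mass conversion chained into daily energy expenditure and
    family-level earthworm consumption estimates, and a consumption-to-area
    model that integrates the overlap between predicted and observed
    breeding home-range bands across an earthworm-availability domain.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
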