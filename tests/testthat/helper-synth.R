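# Small synthetic configurations shared across test files. Sessions are
# generated at reduced cell counts to keep the suite fast; the acceptance
# tests use study-scale populations.

quickHeadFixed <- function(nCells = 30, seed = 1, ...) {
  simulateHeadFixed(synthConfig(nCells = nCells, seed = seed, ...))
}

quickTrack <- function(nCells = 30, seed = 1, ...) {
  simulateTrack(synthConfig(nCells = nCells, design = "freely_moving",
                            seed = seed, ...))
}

# Cache expensive shared fixtures across test files within one run.
.fixtureCache <- new.env(parent = emptyenv())

cachedFixture <- function(key, expr) {
  if (!exists(key, envir = .fixtureCache))
    assign(key, force(expr), envir = .fixtureCache)
  get(key, envir = .fixtureCache)
}
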