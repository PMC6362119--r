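# Shared ABC fixtures.  The study-scale reference table (2e4 rows per
# scenario under the study preset) is expensive, so it is built once per
# test run and reused by every test that needs it.

.fixtures <- new.env(parent = emptyenv())

studyReferenceTable <- function() {
  if (is.null(.fixtures$rt)) {
    preset <- studyPreset()
    .fixtures$rt <- suppressWarnings(
      buildReferenceTable(scenarioLibrary(), preset$prior, preset$config,
                          nPerScenario = 20000L, seed = 904001L))
  }
  .fixtures$rt
}

# a deliberately well-separated scenario set: identical topologies to the
# study scenarios but a narrow Ne prior, so divergence times dominate the
# between-population distances and the three models barely overlap
separatedSetting <- function() {
  preset <- studyPreset()
  prior <- preset$prior
  prior@neLower[] <- 1e3
  prior@neUpper[] <- 2e4
  list(scenarios = scenarioLibrary(), prior = prior, config = preset$config)
}
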