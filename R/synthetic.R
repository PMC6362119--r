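# Study-design emulation: fixture generation under the sampling scheme,
# mutation rate and priors of the four-lineage mountain-refugia design, so
# that every pipeline stage is testable without any external download.

#' Study-design preset: sampling configuration and priors
#'
#' Four populations sampled 10 (KD-EA), 12 (LarNP-CA), 4 (CA) and
#' 13 (WA-Az) individuals (39 in total), a single non-recombining haploid
#' locus of `L` sites (1618 by default, 2370 optional), per-site
#' per-generation mutation rate `mu = 3.9e-8` (0.01306 substitutions per
#' site per Myr at a 3-year generation time), effective sizes with
#' `U(10, 7e5)` priors (one per population plus one ancestral), and fixed
#' divergence times `t1 = 2.46e5`, `t2 = 4.30e5`, `t3 = 4.86e5`,
#' `Tt = 6.86e5` generations.
#'
#' @param L Alignment length in sites.
#' @param timesAreUpperBounds Treat the stated times as upper bounds of
#'   uniform priors instead of fixed values (see [PriorSpec-class]).
#' @return A list with elements `config` ([SampleConfig-class]) and
#'   `prior` ([PriorSpec-class]).
#' @examples
#' sum(studyPreset()$config@sampleSizes)   # 39
#' @export
studyPreset <- function(L = 1618, timesAreUpperBounds = FALSE) {
  ss <- c(10L, 12L, 4L, 13L)
  names(ss) <- STUDY_POPS
  config <- sampleConfig(ss, L = L, mu = 3.9e-8, generationTime = 3)
  parNames <- c(STUDY_POPS, "ancestral")
  prior <- priorSpec(
    neLower = setNames(rep(10, 5), parNames),
    neUpper = setNames(rep(7e5, 5), parNames),
    times = c(t1 = 2.46e5, t2 = 4.30e5, t3 = 4.86e5, Tt = 6.86e5),
    timesAreUpperBounds = timesAreUpperBounds)
  list(config = config, prior = prior)
}

#' Generate one synthetic dataset under the study preset
#'
#' Wraps [simulateDataset()] with the [studyPreset()] conditions; the truth
#' record (scenario, drawn parameters, seed, RNG kind) regenerates the
#' dataset bit for bit.  Optionally writes FASTA, popmap TSV and truth
#' JSON.
#'
#' @param scenarioId One of `"S1_fragmentation"`, `"S2_one_way"`,
#'   `"S3_two_way"`.
#' @param seed Integer seed.
#' @param overrides Named list overriding preset values (`L`, `mu`,
#'   `sampleSizes`, `neLower`, `neUpper`, `times`).
#' @param dir Optional output directory.
#' @return A `"SimulatedDataset"` (see [simulateDataset()]) with an extra
#'   `files` element when `dir` is given.
#' @examples
#' ds <- generateCase("S3_two_way", seed = 42)
#' ds$truth$scenarioId
#' @export
generateCase <- function(scenarioId, seed, overrides = list(), dir = NULL) {
  scns <- scenarioLibrary()
  if (!scenarioId %in% names(scns))
    stop("unknown scenario: ", scenarioId)
  preset <- studyPreset()
  config <- preset$config
  prior <- preset$prior
  for (nm in names(overrides)) {
    val <- overrides[[nm]]
    switch(nm,
           L = { config@L <- val },
           mu = { config@mu <- val },
           sampleSizes = {
             ss <- as.integer(val); names(ss) <- names(val)
             config@sampleSizes <- ss
           },
           neLower = { prior@neLower <- val },
           neUpper = { prior@neUpper <- val },
           times = { prior@times <- val },
           stop("unknown override: ", nm))
  }
  validObject(config); validObject(prior)
  ds <- simulateDataset(scns[[scenarioId]], config, prior, seed = seed)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    stem <- file.path(dir, sprintf("%s_seed%d", scenarioId, seed))
    files <- c(fasta = paste0(stem, ".fasta"),
               popmap = paste0(stem, ".popmap.tsv"),
               truth = paste0(stem, ".truth.json"))
    writePopAlignment(ds$alignment, files[["fasta"]], files[["popmap"]])
    jsonlite::write_json(ds$truth, files[["truth"]], auto_unbox = TRUE,
                         digits = NA)
    ds$files <- files
  }
  ds
}

#' Generate a balanced suite of synthetic datasets
#'
#' `nCases` datasets per scenario with disjoint derived seeds, plus a
#' manifest linking each case to its truth record.
#'
#' @param nCases Cases per scenario.
#' @param seed Base integer seed; case `i` of scenario `s` uses
#'   `seed + 1000*s + i` (kept below 2^31).
#' @param scenarioIds Scenarios to include.
#' @param dir Optional output directory (writes all files plus
#'   `manifest.tsv`).
#' @return A list: `manifest` (data.frame) and `cases` (list of
#'   `"SimulatedDataset"`).
#' @export
generateSuite <- function(nCases, seed, scenarioIds = names(scenarioLibrary()),
                          dir = NULL) {
  stopifnot(nCases >= 1)
  rows <- list()
  cases <- list()
  for (s in seq_along(scenarioIds)) {
    for (i in seq_len(nCases)) {
      caseSeed <- as.integer((seed + 1000L * s + i) %% .Machine$integer.max)
      ds <- generateCase(scenarioIds[s], caseSeed, dir = dir)
      case <- sprintf("%s_case%02d", scenarioIds[s], i)
      cases[[case]] <- ds
      rows[[case]] <- data.frame(
        case = case, scenario = scenarioIds[s], seed = caseSeed,
        fasta = if (!is.null(dir)) ds$files[["fasta"]] else NA_character_,
        popmap = if (!is.null(dir)) ds$files[["popmap"]] else NA_character_,
        truth = if (!is.null(dir)) ds$files[["truth"]] else NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  if (!is.null(dir))
    write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  list(manifest = manifest, cases = cases)
}
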