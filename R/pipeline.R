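# File-format plumbing and end-to-end orchestration: FASTA + popmap in,
# JSON/TSV results out.  Site indices are 0-based internally and 1-based in
# human-readable outputs.

#' Read a sample-to-population map
#'
#' Strict TSV with two columns, `sample_id<TAB>population`, no header.
#' Malformed rows are reported with their line number; duplicate ids are an
#' error naming the id.
#'
#' @param path File path.
#' @return Named character vector (names = sample ids).
#' @export
readPopmap <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad))
    stop("malformed popmap row(s) at line ", paste(bad, collapse = ", "),
         " of ", path)
  ids <- vapply(parts, `[[`, character(1), 1L)
  pops <- vapply(parts, `[[`, character(1), 2L)
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate sample id(s) in popmap: ", paste(unique(dup), collapse = ", "))
  setNames(pops, ids)
}

#' Read a FASTA alignment plus popmap into a PopAlignment
#'
#' @param fastaPath FASTA file (wrapped or unwrapped).
#' @param popmapPath Popmap TSV (see [readPopmap()]).
#' @return A [PopAlignment-class].
#' @export
readPopAlignment <- function(fastaPath, popmapPath) {
  seqs <- Biostrings::readDNAStringSet(fastaPath)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  popmap <- readPopmap(popmapPath)
  missing <- setdiff(names(seqs), names(popmap))
  if (length(missing))
    stop("sample id(s) missing from popmap: ", paste(missing, collapse = ", "))
  PopAlignment(seqs, popmap[names(seqs)])
}

#' Write a PopAlignment as FASTA + popmap TSV
#'
#' @param aln A [PopAlignment-class].
#' @param fastaPath,popmapPath Output paths.
#' @return Invisibly, the paths.
#' @export
writePopAlignment <- function(aln, fastaPath, popmapPath) {
  Biostrings::writeXStringSet(sequences(aln), fastaPath)
  pm <- data.frame(id = names(sequences(aln)),
                   population = as.character(populations(aln)))
  write.table(pm, popmapPath, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(c(fastaPath, popmapPath))
}

#' Write / read a reference table as CSV plus a JSON sidecar
#'
#' The CSV holds one row per simulation (`scenario`, parameter columns,
#' statistic columns); the sidecar records the standardization constants,
#' dropped statistics, prior bounds and seed, so the exact rejection
#' behaviour round-trips.
#'
#' @param rt A [ReferenceTable-class].
#' @param csvPath,jsonPath Output paths (default sidecar:
#'   `<csvPath>.meta.json`).
#' @return Invisibly, the paths.
#' @export
writeReferenceTable <- function(rt, csvPath, jsonPath = paste0(csvPath, ".meta.json")) {
  df <- data.frame(scenario = as.character(rt@scenario), rt@params, rt@stats,
                   check.names = FALSE)
  write.csv(df, csvPath, row.names = FALSE)
  meta <- list(center = as.list(rt@center), scale = as.list(rt@scale),
               dropped = rt@dropped,
               priorLower = as.list(rt@priorLower),
               priorUpper = as.list(rt@priorUpper),
               paramNames = colnames(rt@params),
               statNames = colnames(rt@stats),
               seed = rt@seed)
  jsonlite::write_json(meta, jsonPath, auto_unbox = TRUE, digits = NA)
  invisible(c(csvPath, jsonPath))
}

#' @rdname writeReferenceTable
#' @export
readReferenceTable <- function(csvPath, jsonPath = paste0(csvPath, ".meta.json")) {
  df <- read.csv(csvPath, check.names = FALSE)
  meta <- jsonlite::read_json(jsonPath, simplifyVector = TRUE)
  params <- as.matrix(df[, meta$paramNames, drop = FALSE])
  stats <- as.matrix(df[, meta$statNames, drop = FALSE])
  new("ReferenceTable",
      scenario = factor(df$scenario, levels = unique(df$scenario)),
      params = params, stats = stats,
      center = unlist(meta$center), scale = unlist(meta$scale),
      dropped = as.character(meta$dropped %||% character(0)),
      priorLower = unlist(meta$priorLower), priorUpper = unlist(meta$priorUpper),
      seed = as.numeric(meta$seed %||% NA_real_))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the descriptive stage of the pipeline
#'
#' Chains site classification, haplotype collapsing, diversity indices,
#' p-distances with barcoding-gap partition, AMOVA with pairwise Phi_ST,
#' and the statistical-parsimony network on one alignment.  With a single
#' population the AMOVA stage is skipped with a notice.  All outputs are
#' returned and, if `outDir` is given, written as JSON/TSV together with a
#' run log recording the seed and package version.
#'
#' @param aln A [PopAlignment-class], or `NULL` to read from files.
#' @param fastaPath,popmapPath Input files (used when `aln` is `NULL`).
#' @param outDir Optional output directory.
#' @param nPerm AMOVA permutations (default 10000).
#' @param alpha Parsimony confidence level.
#' @param seed Integer seed; generated (and logged) if missing.
#' @return A list with elements `sites`, `haplotypes`, `diversity`,
#'   `pdist`, `partition`, `amova`, `pairwisePhi`, `network`,
#'   `networkComponents`, `seed`.
#' @export
runDescriptive <- function(aln = NULL, fastaPath = NULL, popmapPath = NULL,
                           outDir = NULL, nPerm = 10000L, alpha = 0.95,
                           seed = NULL) {
  if (is.null(aln)) aln <- readPopAlignment(fastaPath, popmapPath)
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  set.seed(seed)
  res <- list(seed = seed)
  res$sites <- classifySites(aln)
  res$haplotypes <- collapseHaplotypes(aln)
  res$diversity <- diversitySummary(aln)
  res$pdist <- pDistanceMatrix(aln)
  res$partition <- distancePartition(res$pdist, aln)
  if (nlevels(populations(aln)) >= 2L) {
    dm <- pairwiseDifferenceMatrix(aln)
    res$amova <- amovaOneLevel(dm, populations(aln), nPerm = nPerm)
    res$pairwisePhi <- pairwisePhiST(dm, populations(aln), nPerm = nPerm)
  } else {
    message("single population: AMOVA stage skipped")
    res$amova <- NULL
    res$pairwisePhi <- NULL
  }
  res$network <- buildNetwork(aln, alpha = alpha)
  res$networkComponents <- networkComponents(res$network)
  if (!is.null(outDir)) {
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    jsonlite::write_json(
      list(seed = seed, package = "phylogeoABC",
           version = as.character(utils::packageVersion("phylogeoABC")),
           sites = unclass(res$sites),
           diversity = res$diversity[, setdiff(names(res$diversity), "members")],
           amova = if (!is.null(res$amova))
             unclass(res$amova)[c("ssAmong", "ssWithin", "sigma2Among",
                                  "sigma2Within", "pctAmong", "phiST",
                                  "pValue", "nPerm")],
           nComponents = res$networkComponents$nComponents),
      file.path(outDir, "descriptive.json"), auto_unbox = TRUE, digits = NA)
    utils::write.table(res$diversity[, c("population", "n", "p", "S", "pi", "h")],
                       file.path(outDir, "diversity.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    writeNetworkFiles(res$network, file.path(outDir, "network.edges.tsv"),
                      file.path(outDir, "network.graphml"))
  }
  res
}

#' Run the ABC stage of the pipeline
#'
#' Builds (or reuses) a reference table, performs model choice by both the
#' direct and the logistic approach, estimates parameter posteriors under
#' the best-supported scenario, and validates the choice with PODs.
#'
#' @param obs Observed data: a [PopAlignment-class] or a named statistic
#'   vector.
#' @param scenarios,prior,config As in [buildReferenceTable()].
#' @param nPerScenario Reference-table rows per scenario.
#' @param k Direct-rejection acceptance size.
#' @param frac Acceptance fraction for the logistic and regression steps.
#' @param nPods PODs per scenario (default 1000).
#' @param rt Optional prebuilt [ReferenceTable-class] (cached reuse).
#' @param outDir Optional output directory.
#' @param seed Integer seed; generated (and logged) if missing.
#' @return A list: `rt`, `direct`, `logistic`, `best`, `parameters`,
#'   `pods`, `seed`.
#' @export
runABC <- function(obs, scenarios = scenarioLibrary(),
                   prior = studyPreset()$prior, config = studyPreset()$config,
                   nPerScenario = 20000L, k = 500L, frac = 0.01,
                   nPods = 1000L, rt = NULL, outDir = NULL, seed = NULL) {
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  if (k > nPerScenario * length(scenarios))
    stop("k exceeds the requested reference-table size")
  if (is.null(rt))
    rt <- buildReferenceTable(scenarios, prior, config, nPerScenario,
                              seed = seed)
  obsStats <- .obsStats(obs)
  direct <- modelChoiceDirect(rt, obsStats, k = k)
  logistic <- modelChoiceLogistic(rt, obsStats, frac = frac)
  best <- direct$best
  parameters <- estimateParameters(rt, obsStats, scenarioId = best, frac = frac)
  pods <- podsValidation(scenarios, prior, config, rt, focal = best,
                         nPods = nPods, method = "direct", k = k,
                         seed = seed + 1L)
  res <- list(rt = rt, direct = direct, logistic = logistic, best = best,
              parameters = parameters, pods = pods, seed = seed)
  if (!is.null(outDir)) {
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    jsonlite::write_json(
      list(seed = seed, best = best,
           direct = as.list(direct$posterior),
           logistic = as.list(logistic$posterior),
           typeI = pods$typeI, typeII = pods$typeII,
           confusion = as.data.frame.matrix(pods$confusion)),
      file.path(outDir, "abc.json"), auto_unbox = TRUE, digits = NA)
    writeReferenceTable(rt, file.path(outDir, "reference_table.csv"))
  }
  res
}
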