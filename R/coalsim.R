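# R-level surface of the coalescent simulator: scenario construction,
# prior draws, genealogy simulation, Jukes-Cantor sequence evolution.
# The heavy lifting lives in src/coalsim.cpp; all randomness flows through
# R's RNG, so set.seed() makes whole datasets reproducible bit for bit.

STUDY_POPS <- c("KD-EA", "LarNP-CA", "CA", "WA-Az")

#' The three refugial-colonization scenarios
#'
#' Three demographic hypotheses for four allopatric mountain lineages:
#' \describe{
#'   \item{S1_fragmentation}{all four populations split simultaneously from
#'     a single ancestral (single-refugium) population at `Tt`.}
#'   \item{S2_one_way}{serial colonization along one flank:
#'     KD-EA founds LarNP-CA, which founds CA, which founds WA-Az
#'     (backwards: WA-Az joins CA at `t1`, CA joins LarNP-CA at `t2`,
#'     LarNP-CA joins KD-EA at `t3`).}
#'   \item{S3_two_way}{two colonization routes out of KD-EA: a northern
#'     route KD-EA to LarNP-CA to CA and a southern route KD-EA to WA-Az
#'     (backwards: CA joins LarNP-CA at `t1`, WA-Az joins KD-EA at `t2`,
#'     LarNP-CA joins KD-EA at `t3`).}
#' }
#' In every scenario the root population switches to the ancestral
#' effective size at `Tt`.
#'
#' @param popLabels The four population labels, in simulation order.
#' @return Named list of three [DemographicScenario-class] objects.
#' @examples
#' names(scenarioLibrary())
#' @export
scenarioLibrary <- function(popLabels = STUDY_POPS) {
  stopifnot(length(popLabels) == 4L)
  p <- popLabels
  ev <- function(timeName, type, from, to)
    data.frame(timeName = timeName, type = type, from = from, to = to,
               stringsAsFactors = FALSE)
  s1 <- rbind(ev("Tt", "merge", p[2], p[1]),
              ev("Tt", "merge", p[3], p[1]),
              ev("Tt", "merge", p[4], p[1]),
              ev("Tt", "resize", p[1], "ancestral"))
  s2 <- rbind(ev("t1", "merge", p[4], p[3]),
              ev("t2", "merge", p[3], p[2]),
              ev("t3", "merge", p[2], p[1]),
              ev("Tt", "resize", p[1], "ancestral"))
  s3 <- rbind(ev("t1", "merge", p[3], p[2]),
              ev("t2", "merge", p[4], p[1]),
              ev("t3", "merge", p[2], p[1]),
              ev("Tt", "resize", p[1], "ancestral"))
  list(
    S1_fragmentation = new("DemographicScenario", scenarioId = "S1_fragmentation",
                           popLabels = p, events = s1,
                           description = "single-refugium fragmentation: simultaneous split at Tt"),
    S2_one_way = new("DemographicScenario", scenarioId = "S2_one_way",
                     popLabels = p, events = s2,
                     description = "one-way serial colonization along one flank"),
    S3_two_way = new("DemographicScenario", scenarioId = "S3_two_way",
                     popLabels = p, events = s3,
                     description = "two-way colonization via northern and southern routes"))
}

# numeric event matrix for the C++ core; columns: time, type, a, b.
# paramIndex = TRUE encodes resize targets as 0-based indices into the
# parameter vector (for the batch simulator); otherwise params must be the
# named parameter vector and values are substituted.
.eventMatrix <- function(scn, times, params = NULL, paramIndex = FALSE,
                         paramNames = NULL) {
  ev <- scn@events
  popIdx <- function(lab) match(lab, scn@popLabels) - 1L
  if (is.null(paramNames)) paramNames <- c(scn@popLabels, "ancestral")
  tm <- times[ev$timeName]
  if (anyNA(tm)) stop("unresolved event time(s): ",
                      paste(unique(ev$timeName[is.na(tm)]), collapse = ", "))
  typ <- ifelse(ev$type == "merge", 0, 1)
  a <- popIdx(ev$from)
  b <- numeric(nrow(ev))
  for (i in seq_len(nrow(ev))) {
    if (ev$type[i] == "merge") {
      b[i] <- popIdx(ev$to[i])
    } else if (paramIndex) {
      b[i] <- match(ev$to[i], paramNames) - 1L
      if (is.na(b[i])) stop("unknown Ne parameter: ", ev$to[i])
    } else {
      b[i] <- params[[ev$to[i]]]
    }
  }
  mat <- cbind(time = as.numeric(tm), type = typ, a = as.numeric(a), b = b)
  mat[order(mat[, "time"], mat[, "type"]), , drop = FALSE]
}

# resolve divergence times: fixed values, or (optionally) draws from
# U(0, stated value) rejected until t1 < t2 < t3 < Tt
.resolveTimes <- function(prior) {
  if (!prior@timesAreUpperBounds) return(prior@times)
  repeat {
    tt <- stats::setNames(runif(4, 0, prior@times), names(prior@times))
    if (!is.unsorted(tt, strictly = TRUE)) return(tt)
  }
}

#' Draw effective-size parameters from their uniform priors
#'
#' @param prior A [PriorSpec-class].
#' @param n Number of draws.
#' @return An `n x npar` matrix with named columns, one row per draw.
#' @examples
#' pr <- studyPreset()$prior
#' range(drawParams(pr, 100))
#' @export
drawParams <- function(prior, n = 1L) {
  npar <- length(prior@neLower)
  out <- matrix(runif(n * npar, rep(prior@neLower, each = n),
                      rep(prior@neUpper, each = n)), nrow = n)
  colnames(out) <- names(prior@neLower)
  out
}

#' Simulate a coalescent genealogy under a demographic scenario
#'
#' Within each population, every lineage pair coalesces at rate `1/Ne` per
#' generation (haploid convention, so `E[T2] = Ne` and the equilibrium
#' per-site diversity is `2*Ne*mu`); at a merge event all lineages of the
#' derived population move to the source population; the simulation runs to
#' the grand MRCA.
#'
#' @param scenario A [DemographicScenario-class].
#' @param params Named vector of effective sizes (populations plus
#'   `"ancestral"`), e.g. one row of [drawParams()].
#' @param config A [SampleConfig-class]; its `sampleSizes` names must match
#'   the scenario's populations.
#' @param prior A [PriorSpec-class] supplying divergence times.
#' @return A list of class `"Genealogy"`: `parent` (0-based, root `-1`),
#'   `time` (node ages in generations), `tipPop` (factor), `tipIds`.
#' @seealso [genealogyToPhylo()], [evolveSequences()]
#' @export
simulateGenealogy <- function(scenario, params, config, prior) {
  stopifnot(identical(names(config@sampleSizes), scenario@popLabels))
  times <- .resolveTimes(prior)
  ev <- .eventMatrix(scenario, times, params = params)
  ne <- as.numeric(params[scenario@popLabels])
  g <- .sim_genealogy_cpp(config@sampleSizes, ne, ev)
  tipPop <- factor(scenario@popLabels[g$tipPop + 1L], levels = scenario@popLabels)
  ids <- paste0(as.character(tipPop), "_",
                unlist(lapply(config@sampleSizes, seq_len)))
  structure(list(parent = g$parent, time = g$time, tipPop = tipPop,
                 tipIds = ids, times = times, scenarioId = scenario@scenarioId),
            class = "Genealogy")
}

#' Convert a simulated genealogy to an ape "phylo" tree
#'
#' @param gen A `"Genealogy"` from [simulateGenealogy()].
#' @return An [ape::phylo] object with branch lengths in generations.
#' @export
genealogyToPhylo <- function(gen) {
  n <- length(gen$tipIds)
  apeId <- function(v) ifelse(v < n, v + 1L, 3L * n - v - 1L)
  child <- 0:(2L * n - 3L)
  edge <- cbind(apeId(gen$parent[child + 1L]), apeId(child))
  len <- gen$time[gen$parent[child + 1L] + 1L] - gen$time[child + 1L]
  tr <- list(edge = edge, edge.length = len, tip.label = gen$tipIds,
             Nnode = n - 1L)
  class(tr) <- "phylo"
  ape::reorder.phylo(tr, "cladewise")
}

#' Evolve sequences along a genealogy (Jukes-Cantor)
#'
#' Mutations are placed as Poisson(`mu` x branch length x `L`) events per
#' branch, each at a uniform site and to a uniform different base, starting
#' from a random equal-frequency ancestral sequence.
#'
#' @param gen A `"Genealogy"` from [simulateGenealogy()].
#' @param config A [SampleConfig-class] (uses `L` and `mu`).
#' @return A [PopAlignment-class] with the genealogy's tip populations.
#' @export
evolveSequences <- function(gen, config) {
  n <- length(gen$tipIds)
  m <- .evolve_sequences_cpp(gen$parent, gen$time, n, as.integer(config@L),
                             config@mu)
  .intMatrixToAlignment(m, gen$tipIds, gen$tipPop)
}

# L x n integer (0..3) matrix -> PopAlignment
.intMatrixToAlignment <- function(m, ids, pop) {
  seqs <- vapply(seq_len(ncol(m)),
                 function(i) paste(BASES[m[, i] + 1L], collapse = ""),
                 character(1))
  names(seqs) <- ids
  PopAlignment(Biostrings::DNAStringSet(seqs), pop)
}

#' Simulate a full dataset under a scenario
#'
#' Draws parameters from the prior (unless supplied), simulates a genealogy
#' and evolves sequences, returning the alignment together with a truth
#' record sufficient to regenerate it.
#'
#' @param scenario A [DemographicScenario-class].
#' @param config A [SampleConfig-class].
#' @param prior A [PriorSpec-class].
#' @param params Optional named parameter vector; drawn from `prior` if
#'   `NULL`.
#' @param seed Optional integer seed (recorded in the truth record).
#' @return A list of class `"SimulatedDataset"`: `alignment`
#'   ([PopAlignment-class]) and `truth` (scenario id, parameters, times,
#'   seed, L, mu, RNG kind).
#' @examples
#' preset <- studyPreset()
#' scn <- scenarioLibrary()$S3_two_way
#' ds <- simulateDataset(scn, preset$config, preset$prior, seed = 1)
#' ds$alignment
#' @export
simulateDataset <- function(scenario, config, prior, params = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(params)) params <- drawParams(prior, 1L)[1L, ]
  gen <- simulateGenealogy(scenario, params, config, prior)
  aln <- evolveSequences(gen, config)
  truth <- list(scenarioId = scenario@scenarioId,
                params = as.list(params),
                times = as.list(gen$times),
                seed = seed, L = config@L, mu = config@mu,
                generationTime = config@generationTime,
                rngKind = RNGkind()[1])
  structure(list(alignment = aln, truth = truth), class = "SimulatedDataset")
}

#' @export
print.SimulatedDataset <- function(x, ...) {
  cat("SimulatedDataset under", x$truth$scenarioId, "\n")
  show(x$alignment)
  invisible(x)
}
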