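#' Aligned haploid sequences with a population partition
#'
#' `PopAlignment` couples an equal-width [Biostrings::DNAStringSet] (one
#' sequence per individual, unique names) with a population label per
#' individual.  It is the central observed/simulated data container: every
#' descriptive statistic, the AMOVA, the haplotype network and the ABC
#' summary statistics operate on it.
#'
#' @slot seqs A [Biostrings::DNAStringSet] of equal-width sequences over
#'   the alphabet A, C, G, T, N, `-`; names are the sample identifiers.
#' @slot population A factor parallel to `seqs` giving each individual's
#'   population; its levels fix the population ordering used throughout
#'   (summary-statistic order, scenario population order).
#'
#' @seealso [readPopAlignment()], [diversitySummary()], [computeSumstats()]
#' @export
setClass("PopAlignment",
         representation(seqs = "ANY", population = "factor"))

setValidity("PopAlignment", function(object) {
  msg <- character()
  if (!is(object@seqs, "DNAStringSet"))
    msg <- c(msg, "seqs must be a DNAStringSet")
  else {
    w <- Biostrings::width(object@seqs)
    if (length(w) == 0L) msg <- c(msg, "alignment must contain sequences")
    if (length(unique(w)) > 1L) msg <- c(msg, "sequences must have equal length")
    if (length(w) && w[1] < 1L) msg <- c(msg, "alignment length must be >= 1")
    nm <- names(object@seqs)
    if (is.null(nm) || anyNA(nm) || any(nm == ""))
      msg <- c(msg, "all sequences must be named")
    else if (anyDuplicated(nm))
      msg <- c(msg, "sequence names must be unique")
    if (length(object@population) != length(object@seqs))
      msg <- c(msg, "population must map every sequence")
    if (anyNA(object@population))
      msg <- c(msg, "population labels must not be NA")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a PopAlignment
#'
#' @param seqs A [Biostrings::DNAStringSet] (or named character vector of
#'   equal-length sequences).
#' @param population Population label per sequence, either unnamed and
#'   parallel to `seqs` or named by sample id.
#' @return A [PopAlignment-class] object.
#' @examples
#' seqs <- c(a1 = "ACGT", a2 = "ACGA", b1 = "TCGA")
#' PopAlignment(seqs, c("A", "A", "B"))
#' @export
PopAlignment <- function(seqs, population) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  if (!is.null(names(population)) && !is.null(names(seqs))) {
    missing <- setdiff(names(seqs), names(population))
    if (length(missing))
      stop("unmapped sample id(s): ", paste(missing, collapse = ", "))
    population <- population[names(seqs)]
  }
  if (!is.factor(population))
    population <- factor(population, levels = unique(as.character(population)))
  new("PopAlignment", seqs = seqs, population = population)
}

setMethod("show", "PopAlignment", function(object) {
  cat("PopAlignment:", length(object@seqs), "sequences x",
      if (length(object@seqs)) Biostrings::width(object@seqs)[1] else 0, "sites\n")
  tab <- table(object@population)
  cat("populations:",
      paste(sprintf("%s (%d)", names(tab), as.integer(tab)), collapse = ", "), "\n")
})

#' @describeIn PopAlignment-class the underlying `DNAStringSet`
#' @param x,object A `PopAlignment`.
#' @export
setGeneric("sequences", function(x) standardGeneric("sequences"))

#' @rdname PopAlignment-class
#' @export
setMethod("sequences", "PopAlignment", function(x) x@seqs)

#' @describeIn PopAlignment-class the population factor (named by sample id)
#' @export
setGeneric("populations", function(x) standardGeneric("populations"))

#' @rdname PopAlignment-class
#' @export
setMethod("populations", "PopAlignment", function(x) {
  p <- x@population
  names(p) <- names(x@seqs)
  p
})

#' @describeIn PopAlignment-class number of sequences
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname PopAlignment-class
#' @export
setMethod("nSamples", "PopAlignment", function(x) length(x@seqs))

#' @describeIn PopAlignment-class alignment length in sites
#' @export
setGeneric("alnLength", function(x) standardGeneric("alnLength"))

#' @rdname PopAlignment-class
#' @export
setMethod("alnLength", "PopAlignment", function(x)
  if (length(x@seqs)) Biostrings::width(x@seqs)[1] else 0L)


#' Sampling and mutation configuration for coalescent simulation
#'
#' Holds the per-population sample sizes, alignment length, per-site
#' per-generation mutation rate and the generation time (metadata used only
#' when converting generations to years).
#'
#' @slot sampleSizes Named integer vector of haploid sample sizes; the names
#'   and their order define the populations.
#' @slot L Alignment length in sites.
#' @slot mu Per-site per-generation mutation rate.
#' @slot generationTime Generation time in years (metadata).
#' @slot model Substitution model label; `"JC"` is implemented.
#' @export
setClass("SampleConfig",
         representation(sampleSizes = "integer", L = "numeric", mu = "numeric",
                        generationTime = "numeric", model = "character"))

setValidity("SampleConfig", function(object) {
  msg <- character()
  if (is.null(names(object@sampleSizes)) || anyDuplicated(names(object@sampleSizes)))
    msg <- c(msg, "sampleSizes must have unique names")
  if (any(object@sampleSizes < 1L)) msg <- c(msg, "all sample sizes must be >= 1")
  if (object@L < 1) msg <- c(msg, "L must be >= 1")
  if (object@mu < 0) msg <- c(msg, "mu must be >= 0")
  if (!object@model %in% "JC") msg <- c(msg, "only the JC model is implemented")
  if (length(msg)) msg else TRUE
})

#' @rdname SampleConfig-class
#' @param sampleSizes,L,mu,generationTime,model See slot descriptions.
#' @return A `SampleConfig`.
#' @export
sampleConfig <- function(sampleSizes, L, mu, generationTime = 3, model = "JC") {
  ss <- as.integer(sampleSizes)
  names(ss) <- names(sampleSizes)
  new("SampleConfig", sampleSizes = ss,
      L = as.numeric(L), mu = as.numeric(mu),
      generationTime = as.numeric(generationTime), model = model)
}

setMethod("show", "SampleConfig", function(object) {
  cat("SampleConfig:", sum(object@sampleSizes), "samples,",
      "L =", object@L, "sites, mu =", format(object@mu), "\n")
  print(object@sampleSizes)
})


#' Uniform priors and divergence-time settings
#'
#' Effective sizes get independent uniform priors (one per sampled
#' population plus one ancestral size).  Divergence times `t1 < t2 < t3 < Tt`
#' are fixed values by default; optionally each stated value is treated as
#' the upper bound of a `U(0, value)` prior (draws are rejected until the
#' ordering holds).
#'
#' @slot neLower,neUpper Named numeric vectors of uniform prior bounds for
#'   the effective sizes (names: populations plus `"ancestral"`).
#' @slot times Named numeric vector `c(t1=, t2=, t3=, Tt=)`, generations.
#' @slot timesAreUpperBounds Logical; see Details.
#' @slot sizeChange Logical; whether each population may undergo a discrete
#'   size change at a uniform random time on its branch (off by default).
#' @export
setClass("PriorSpec",
         representation(neLower = "numeric", neUpper = "numeric",
                        times = "numeric", timesAreUpperBounds = "logical",
                        sizeChange = "logical"))

setValidity("PriorSpec", function(object) {
  msg <- character()
  if (length(object@neLower) != length(object@neUpper))
    msg <- c(msg, "neLower and neUpper must have the same length")
  if (any(object@neLower >= object@neUpper))
    msg <- c(msg, "each lower bound must be below its upper bound")
  if (any(object@neLower <= 0)) msg <- c(msg, "Ne bounds must be positive")
  tn <- names(object@times)
  if (!identical(tn, c("t1", "t2", "t3", "Tt")))
    msg <- c(msg, "times must be named t1, t2, t3, Tt")
  else if (is.unsorted(object@times, strictly = TRUE))
    msg <- c(msg, "times must satisfy t1 < t2 < t3 < Tt")
  if (length(msg)) msg else TRUE
})

#' @rdname PriorSpec-class
#' @param neLower,neUpper,times,timesAreUpperBounds,sizeChange See slots.
#' @return A `PriorSpec`.
#' @export
priorSpec <- function(neLower, neUpper, times,
                      timesAreUpperBounds = FALSE, sizeChange = FALSE) {
  new("PriorSpec", neLower = neLower, neUpper = neUpper, times = times,
      timesAreUpperBounds = timesAreUpperBounds, sizeChange = sizeChange)
}

setMethod("show", "PriorSpec", function(object) {
  cat("PriorSpec:", length(object@neLower), "Ne parameters ~ U(",
      format(object@neLower[1]), ",", format(object@neUpper[1]), ")\n")
  cat("times (generations):",
      paste(names(object@times), format(object@times, scientific = TRUE),
            sep = "=", collapse = ", "),
      if (object@timesAreUpperBounds) "(upper bounds of U(0, .))" else "(fixed)",
      "\n")
})


#' A demographic scenario: populations linked by divergence events
#'
#' Events are encoded forward-in-file but apply backward in time: a *merge*
#' moves the lineages of a derived population into its source population at
#' the stated time; a *resize* changes a population's effective size (used
#' to switch the root population to the ancestral size at `Tt`).  Time names
#' (`t1`..`Tt`) are resolved against a [PriorSpec-class] at simulation time.
#'
#' @slot scenarioId Scenario identifier.
#' @slot popLabels The sampled population labels, in simulation order.
#' @slot events A data.frame with columns `timeName`, `type`
#'   (`"merge"`/`"resize"`), `from`, `to` (for resize, `to` names the Ne
#'   parameter to switch to, e.g. `"ancestral"`).
#' @slot description Free-text description.
#' @seealso [scenarioLibrary()]
#' @export
setClass("DemographicScenario",
         representation(scenarioId = "character", popLabels = "character",
                        events = "data.frame", description = "character"))

setValidity("DemographicScenario", function(object) {
  msg <- character()
  ev <- object@events
  need <- c("timeName", "type", "from", "to")
  if (!all(need %in% names(ev))) {
    msg <- c(msg, "events must have columns timeName, type, from, to")
    return(msg)
  }
  if (!all(ev$type %in% c("merge", "resize")))
    msg <- c(msg, "event type must be merge or resize")
  mg <- ev[ev$type == "merge", , drop = FALSE]
  if (!all(mg$from %in% object@popLabels) || !all(mg$to %in% object@popLabels))
    msg <- c(msg, "merge events must reference sampled population labels")
  # every non-root population must eventually merge away into a single root
  merged <- unique(mg$from)
  roots <- setdiff(object@popLabels, merged)
  if (length(roots) != 1L)
    msg <- c(msg, "merge events must resolve all populations into one root")
  if (length(msg)) msg else TRUE
})

setMethod("show", "DemographicScenario", function(object) {
  cat("DemographicScenario", object@scenarioId, "\n ", object@description, "\n")
  ev <- object@events
  for (i in seq_len(nrow(ev)))
    cat(sprintf("  %-4s %-6s %s -> %s\n", ev$timeName[i], ev$type[i],
                ev$from[i], ev$to[i]))
})


#' Reference table of simulated (scenario, parameters, summary statistics)
#'
#' The stored rows drive ABC rejection: statistics are standardized by their
#' per-column median and MAD computed from the table itself; statistics with
#' zero MAD are excluded from the Euclidean distance.
#'
#' @slot scenario Factor of generating scenario per row.
#' @slot params Numeric matrix of drawn parameters (columns named).
#' @slot stats Numeric matrix of summary statistics (columns named).
#' @slot center,scale Named per-statistic median and MAD.
#' @slot dropped Statistics excluded from distances (zero MAD).
#' @slot priorLower,priorUpper Prior bounds of the parameter columns.
#' @slot seed The seed the table was built under (`NA` if none given).
#' @seealso [buildReferenceTable()], [modelChoiceDirect()]
#' @export
setClass("ReferenceTable",
         representation(scenario = "factor", params = "matrix", stats = "matrix",
                        center = "numeric", scale = "numeric",
                        dropped = "character",
                        priorLower = "numeric", priorUpper = "numeric",
                        seed = "numeric"))

setValidity("ReferenceTable", function(object) {
  msg <- character()
  n <- length(object@scenario)
  if (nrow(object@params) != n || nrow(object@stats) != n)
    msg <- c(msg, "scenario, params and stats must have one row per simulation")
  if (length(object@center) != ncol(object@stats) ||
      length(object@scale) != ncol(object@stats))
    msg <- c(msg, "center/scale must match the statistics columns")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ReferenceTable", function(object) {
  cat("ReferenceTable:", length(object@scenario), "simulations,",
      ncol(object@stats), "summary statistics\n")
  print(table(object@scenario))
  if (length(object@dropped))
    cat("dropped (zero MAD):", paste(object@dropped, collapse = ", "), "\n")
})

#' @describeIn ReferenceTable-class number of simulated rows
#' @param x,object A `ReferenceTable`.
#' @export
setMethod("length", "ReferenceTable", function(x) length(x@scenario))


#' Statistical-parsimony haplotype network
#'
#' Nodes are sampled haplotypes (with observed frequencies and population
#' composition) plus inferred intermediates (frequency 0); every edge spans
#' exactly one mutational step.  Connections whose mutational distance
#' exceeds the parsimony limit are never made, so the graph may fall apart
#' into several components.
#'
#' @slot graph An [igraph::igraph] with the expanded single-step edges.
#' @slot nodes data.frame of all nodes: `id`, `type` (sampled/inferred),
#'   `frequency`, `populations`.
#' @slot edges data.frame of single-step edges: `node1`, `node2`, `steps`.
#' @slot connections data.frame of haplotype-level connections made
#'   (`hap1`, `hap2`, `steps`).
#' @slot hamming Mutational (Hamming) distance matrix between sampled
#'   haplotypes on the retained sites.
#' @slot limit The connection limit used (integer steps).
#' @slot haplotypes The haplotype table the network was built from.
#' @seealso [buildNetwork()], [networkComponents()]
#' @export
setClass("HaplotypeNetwork",
         representation(graph = "ANY", nodes = "data.frame",
                        edges = "data.frame", connections = "data.frame",
                        hamming = "matrix", limit = "integer",
                        haplotypes = "data.frame"))

setMethod("show", "HaplotypeNetwork", function(object) {
  ns <- sum(object@nodes$type == "sampled")
  ni <- sum(object@nodes$type == "inferred")
  cat("HaplotypeNetwork:", ns, "sampled haplotypes,", ni,
      "inferred intermediates,", nrow(object@edges), "single-step edges\n")
  cat("connection limit:", object@limit, "steps;",
      igraph::count_components(object@graph), "component(s)\n")
})
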