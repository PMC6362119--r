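# Statistical parsimony: haplotypes are connected in increasing order of
# mutational (Hamming) distance, never beyond the number of steps that can
# be assumed non-homoplastic at the chosen confidence level.

#' Probability that j observed differences are non-homoplastic
#'
#' For two sequences of `L` sites differing at `j` sites, models per-site
#' mutation counts as Poisson under Jukes-Cantor, estimates the mutation
#' intensity from the observed proportion of differing sites
#' (`lambda = -3/4 * log(1 - 4j/(3L))`) and returns the probability that no
#' site experienced more than one mutation given the observed pattern:
#' `[P(K=1 | differ)]^j * [P(K=0 | same)]^(L-j)`.
#'
#' @param j Number of observed differences (mutational steps).
#' @param L Number of sites.
#' @return Probability in `[0, 1]` (`1` for `j = 0`, `0` once `j >= 3L/4`).
#' @export
parsimonyProbability <- function(j, L) {
  stopifnot(L >= 2, j >= 0)
  vapply(j, function(jj) {
    if (jj == 0) return(1)
    x <- 4 * jj / (3 * L)
    if (x >= 1) return(0)
    lambda <- -0.75 * log(1 - x)
    pd <- jj / L                       # = 3/4 (1 - exp(-4 lambda / 3))
    logP <- jj * (log(lambda) - lambda - log(pd)) +
      (L - jj) * (-lambda - log(1 - pd))
    exp(logP)
  }, numeric(1))
}

#' 95% parsimony connection limit
#'
#' The largest number of mutational steps `j` whose probability of being
#' non-homoplastic ([parsimonyProbability()]) is at least `alpha`.  At least
#' one step is always allowed.  The limit is non-decreasing in `L`.
#'
#' @param L Number of sites (>= 2).
#' @param alpha Confidence level in `(0, 1)`; default `0.95`.
#' @return A list of class `"ParsimonyLimit"`: `maxSteps`, `alpha`, `L`.
#' @examples
#' parsimonyLimit(1618)$maxSteps
#' @export
parsimonyLimit <- function(L, alpha = 0.95) {
  stopifnot(L >= 2)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must be in (0, 1)")
  j <- 0L
  while (j < L && parsimonyProbability(j + 1L, L) >= alpha) j <- j + 1L
  structure(list(maxSteps = max(j, 1L), alpha = alpha, L = as.integer(L)),
            class = "ParsimonyLimit")
}

#' @export
print.ParsimonyLimit <- function(x, ...) {
  cat("parsimony connection limit:", x$maxSteps, "steps (alpha =", x$alpha,
      ", L =", x$L, "sites)\n")
  invisible(x)
}

.hammingFromStrings <- function(seqs) {
  H <- length(seqs)
  if (H == 0L) stop("no haplotypes")
  mat <- do.call(rbind, strsplit(seqs, ""))
  D <- matrix(0L, H, H, dimnames = list(names(seqs), names(seqs)))
  if (H >= 2L)
    for (i in seq_len(H - 1L))
      for (j in (i + 1L):H) {
        d <- sum(mat[i, ] != mat[j, ])
        D[i, j] <- d; D[j, i] <- d
      }
  D
}

#' Build a statistical-parsimony (TCS-style) haplotype network
#'
#' Haplotype pairs are connected greedily in increasing order of mutational
#' distance (minimum-spanning-network style).  Within one distance class,
#' every pair joining two components that were distinct at the start of the
#' class is connected, so equal-cost alternatives are all retained (loops
#' are kept, not resolved).  Connections longer than the parsimony limit are
#' forbidden; a connection of `d` steps inserts `d - 1` inferred
#' intermediate haplotypes so that every edge spans exactly one step.
#'
#' @param x A [PopAlignment-class], or a haplotype table from
#'   [collapseHaplotypes()].
#' @param limit Connection limit in steps; default
#'   `parsimonyLimit(L, alpha)` where `L` is the alignment length.
#' @param alpha Confidence level for the default limit.
#' @return A [HaplotypeNetwork-class].
#' @examples
#' aln <- PopAlignment(c(a = "AAAA", b = "AAAT", c = "AATT"), rep("p", 3))
#' net <- buildNetwork(aln)
#' networkComponents(net)$nComponents   # 1: a chain a-b-c
#' @export
buildNetwork <- function(x, limit = NULL, alpha = 0.95) {
  popComp <- NULL
  if (is(x, "PopAlignment")) {
    ht <- collapseHaplotypes(x)
    pop <- populations(x)
    assignment <- attr(ht, "assignment")
    popComp <- vapply(ht$haplotype, function(h) {
      tab <- table(as.character(pop[names(assignment)[assignment == h]]))
      paste(sprintf("%s:%d", names(tab), as.integer(tab)), collapse = ",")
    }, character(1))
    Lfull <- alnLength(x)
  } else {
    ht <- x
    if (is.null(attr(ht, "seqs"))) stop("x must be a PopAlignment or a haplotype table")
    Lfull <- nchar(attr(ht, "seqs")[1])
    popComp <- rep("", nrow(ht))
  }
  seqs <- attr(ht, "seqs")
  if (is.null(limit)) limit <- parsimonyLimit(max(Lfull, 2), alpha)
  maxSteps <- if (inherits(limit, "ParsimonyLimit")) limit$maxSteps else as.integer(limit)
  if (maxSteps < 1L) stop("connection limit must be >= 1")
  H <- nrow(ht)
  D <- .hammingFromStrings(seqs)
  comp <- seq_len(H)
  connections <- data.frame(hap1 = character(), hap2 = character(),
                            steps = integer(), stringsAsFactors = FALSE)
  for (d in seq_len(min(maxSteps, if (H >= 2L) max(D) else 0L))) {
    snapshot <- comp
    pairs <- which(D == d & upper.tri(D), arr.ind = TRUE)
    if (nrow(pairs) == 0L) next
    pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
    for (r in seq_len(nrow(pairs))) {
      i <- pairs[r, 1L]; j <- pairs[r, 2L]
      if (snapshot[i] != snapshot[j]) {
        connections <- rbind(connections,
                             data.frame(hap1 = ht$haplotype[i],
                                        hap2 = ht$haplotype[j],
                                        steps = d, stringsAsFactors = FALSE))
        old <- comp[j]
        comp[comp == old] <- comp[i]
      }
    }
  }
  # expand multi-step connections into single-step edges via inferred nodes
  edges <- list()
  inferred <- character()
  for (r in seq_len(nrow(connections))) {
    a <- connections$hap1[r]; b <- connections$hap2[r]
    d <- connections$steps[r]
    ends <- sort(c(a, b))               # lexicographic tie-break for naming
    if (d == 1L) {
      edges[[length(edges) + 1L]] <- data.frame(node1 = a, node2 = b,
                                                steps = 1L, stringsAsFactors = FALSE)
    } else {
      mids <- sprintf("iv_%s_%s_%d", ends[1], ends[2], seq_len(d - 1L))
      inferred <- c(inferred, mids)
      path <- c(ends[1], mids, ends[2])
      for (k in seq_len(length(path) - 1L))
        edges[[length(edges) + 1L]] <- data.frame(node1 = path[k],
                                                  node2 = path[k + 1L],
                                                  steps = 1L, stringsAsFactors = FALSE)
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(node1 = character(), node2 = character(), steps = integer(),
               stringsAsFactors = FALSE)
  nodes <- rbind(
    data.frame(id = ht$haplotype, type = "sampled", frequency = ht$count,
               populations = popComp, stringsAsFactors = FALSE),
    if (length(inferred))
      data.frame(id = inferred, type = "inferred", frequency = 0L,
                 populations = "", stringsAsFactors = FALSE))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE, vertices = nodes)
  new("HaplotypeNetwork", graph = g, nodes = nodes, edges = edges,
      connections = connections, hamming = D,
      limit = as.integer(maxSteps), haplotypes = ht)
}

#' Components of a haplotype network
#'
#' Partition of the sampled haplotypes into connected subnetworks, with the
#' population composition of each component and the minimum mutational
#' (Hamming) distance across each component pair.
#'
#' @param net A [HaplotypeNetwork-class].
#' @return A list: `nComponents`, `members` (list of sampled haplotype ids),
#'   `populations` (aggregate count string per component), `stepsBetween`
#'   (matrix of minimum Hamming distances across the cut).
#' @export
networkComponents <- function(net) {
  cmp <- igraph::components(net@graph)
  memb <- cmp$membership
  sampled <- net@nodes$id[net@nodes$type == "sampled"]
  byComp <- split(sampled, memb[sampled])
  names(byComp) <- paste0("C", seq_along(byComp))
  popAgg <- vapply(byComp, function(ids) {
    rows <- match(ids, net@nodes$id)
    parts <- net@nodes$populations[rows]
    parts <- parts[parts != ""]
    if (!length(parts)) return("")
    items <- unlist(strsplit(parts, ","))
    kv <- do.call(rbind, strsplit(items, ":"))
    agg <- tapply(as.integer(kv[, 2L]), kv[, 1L], sum)
    paste(sprintf("%s:%d", names(agg), as.integer(agg)), collapse = ",")
  }, character(1))
  K <- length(byComp)
  sb <- matrix(NA_real_, K, K, dimnames = list(names(byComp), names(byComp)))
  diag(sb) <- 0
  if (K >= 2L)
    for (a in seq_len(K - 1L))
      for (b in (a + 1L):K)
        sb[a, b] <- sb[b, a] <- min(net@hamming[byComp[[a]], byComp[[b]]])
  list(nComponents = K, members = byComp, populations = popAgg,
       stepsBetween = sb)
}

#' Write a haplotype network to edge-list TSV and GraphML
#'
#' @param net A [HaplotypeNetwork-class].
#' @param edgePath Path for the `node1 node2 steps` TSV (also writes a
#'   `<edgePath>.nodes.tsv` node table).
#' @param graphmlPath Optional path for a GraphML export.
#' @return Invisibly, the paths written.
#' @export
writeNetworkFiles <- function(net, edgePath, graphmlPath = NULL) {
  write.table(net@edges, edgePath, sep = "\t", quote = FALSE,
              row.names = FALSE)
  nodesPath <- paste0(edgePath, ".nodes.tsv")
  write.table(net@nodes, nodesPath, sep = "\t", quote = FALSE,
              row.names = FALSE)
  paths <- c(edgePath, nodesPath)
  if (!is.null(graphmlPath)) {
    igraph::write_graph(net@graph, graphmlPath, format = "graphml")
    paths <- c(paths, graphmlPath)
  }
  invisible(paths)
}
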