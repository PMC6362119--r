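BASES <- c("A", "C", "G", "T")

# character matrix (individuals x sites) from a PopAlignment
.alnCharMatrix <- function(aln) {
  m <- as.matrix(sequences(aln))
  rownames(m) <- names(sequences(aln))
  m
}

# columns free of gaps/ambiguity across the whole sample ("complete deletion")
.retainedSites <- function(m) {
  ok <- matrix(m %in% BASES, nrow = nrow(m))
  which(colSums(ok) == nrow(m))
}

#' Classify alignment sites
#'
#' Partitions the sites of an alignment into invariable, singleton,
#' parsimony-informative and excluded.  Sites containing a gap, `N` or any
#' other ambiguity anywhere in the sample are excluded (complete deletion,
#' the DnaSP convention).  A retained site is parsimony-informative iff at
#' least two character states are each carried by at least two sequences;
#' variable sites that are not informative are singletons.  The four
#' categories always sum to the alignment length.
#'
#' @param aln A [PopAlignment-class] (or `DNAStringSet`).
#' @return A list of class `"SiteClassification"` with counts `invariable`,
#'   `singleton`, `parsimonyInformative`, `excluded` and the total `L`.
#' @examples
#' aln <- PopAlignment(c(a = "AACA", b = "AACA", c = "ACCG", d = "ACCG"),
#'                     rep("p", 4))
#' classifySites(aln)
#' @export
classifySites <- function(aln) {
  if (is(aln, "DNAStringSet")) aln <- PopAlignment(aln, rep("pop", length(aln)))
  m <- .alnCharMatrix(aln)
  if (nrow(m) == 0L) stop("empty alignment")
  L <- ncol(m)
  keep <- .retainedSites(m)
  excluded <- L - length(keep)
  inv <- sing <- pinf <- 0L
  for (s in keep) {
    tab <- tabulate(factor(m[, s], levels = BASES), nbins = 4L)
    nstates <- sum(tab > 0L)
    if (nstates == 1L) inv <- inv + 1L
    else if (sum(tab >= 2L) >= 2L) pinf <- pinf + 1L
    else sing <- sing + 1L
  }
  structure(list(invariable = inv, singleton = sing,
                 parsimonyInformative = pinf, excluded = excluded, L = L),
            class = "SiteClassification")
}

#' @export
print.SiteClassification <- function(x, ...) {
  cat("Site classification (", x$L, " sites):\n", sep = "")
  cat("  invariable:           ", x$invariable, "\n")
  cat("  singleton:            ", x$singleton, "\n")
  cat("  parsimony-informative:", x$parsimonyInformative, "\n")
  cat("  excluded (missing):   ", x$excluded, "\n")
  invisible(x)
}

#' Collapse sequences into haplotypes
#'
#' Sequences identical on the retained sites (complete deletion of columns
#' with gaps or ambiguity) share one haplotype.  Haplotypes are numbered in
#' order of first appearance.
#'
#' @param aln A [PopAlignment-class].
#' @return A data.frame with one row per haplotype: `haplotype`, `count`,
#'   `frequency`, `members` (list column of sample ids).  Attributes:
#'   `assignment` (sample id to haplotype), `seqs` (haplotype strings over
#'   retained sites), `retained` (retained site indices).
#' @examples
#' aln <- PopAlignment(c(a = "AAAA", b = "AAAT", c = "AAAT"), rep("p", 3))
#' collapseHaplotypes(aln)
#' @export
collapseHaplotypes <- function(aln) {
  m <- .alnCharMatrix(aln)
  if (nrow(m) == 0L) stop("empty alignment")
  keep <- .retainedSites(m)
  mk <- m[, keep, drop = FALSE]
  key <- apply(mk, 1L, paste, collapse = "")
  lev <- unique(key)
  idx <- match(key, lev)
  hap <- paste0("H", seq_along(lev))
  members <- split(rownames(m), idx)
  counts <- lengths(members)
  out <- data.frame(haplotype = hap, count = as.integer(counts),
                    frequency = as.numeric(counts) / nrow(m),
                    stringsAsFactors = FALSE)
  out$members <- unname(members)
  assignment <- hap[idx]
  names(assignment) <- rownames(m)
  attr(out, "assignment") <- assignment
  attr(out, "seqs") <- stats::setNames(lev, hap)
  attr(out, "retained") <- keep
  out
}

# pairwise difference counts on a character matrix (no missing data)
.pairDiffCounts <- function(mk) {
  n <- nrow(mk)
  D <- matrix(0L, n, n, dimnames = list(rownames(mk), rownames(mk)))
  if (n >= 2L)
    for (i in seq_len(n - 1L))
      for (j in (i + 1L):n) {
        d <- sum(mk[i, ] != mk[j, ])
        D[i, j] <- d; D[j, i] <- d
      }
  D
}

.divOne <- function(mk) {
  n <- nrow(mk)
  Lr <- ncol(mk)
  if (n < 2L) {
    return(list(n = n, p = if (n >= 1L) 1L else 0L, S = 0L, pi = 0,
                h = 0, degenerate = TRUE))
  }
  S <- sum(apply(mk, 2L, function(col) length(unique(col)) > 1L))
  D <- .pairDiffCounts(mk)
  mpd <- mean(D[upper.tri(D)])
  pi <- if (Lr > 0L) mpd / Lr else 0
  key <- apply(mk, 1L, paste, collapse = "")
  f <- as.numeric(table(key)) / n
  h <- n / (n - 1) * (1 - sum(f^2))
  list(n = n, p = length(f), S = as.integer(S), pi = pi, h = h,
       degenerate = FALSE)
}

#' Per-population diversity indices
#'
#' Computes, on the sites retained under complete deletion: sample size `n`,
#' haplotype count `p`, segregating (polymorphic) sites `S`, nucleotide
#' diversity `pi` (mean per-site pairwise difference) and Nei's unbiased
#' haplotype diversity `h = n/(n-1) * (1 - sum f_i^2)`.  Populations with
#' `n < 2` are flagged degenerate and report `pi = h = 0`.
#'
#' @param aln A [PopAlignment-class].
#' @param byPopulation If `TRUE` (default) one row per population plus a
#'   pooled `Total` row; otherwise the pooled row only.
#' @return A data.frame with columns `population`, `n`, `p`, `S`, `pi`, `h`,
#'   `degenerate`.
#' @examples
#' aln <- PopAlignment(c(a = "AAAAAAAAAA", b = "AAAAAAAAAT"), c("p", "p"))
#' diversitySummary(aln)   # S = 1, pi = 0.1, h = 1
#' @export
diversitySummary <- function(aln, byPopulation = TRUE) {
  m <- .alnCharMatrix(aln)
  if (nrow(m) < 1L) stop("empty alignment")
  keep <- .retainedSites(m)
  mk <- m[, keep, drop = FALSE]
  pop <- populations(aln)
  rows <- list()
  if (byPopulation)
    for (g in levels(pop)) {
      r <- .divOne(mk[as.character(pop) == g, , drop = FALSE])
      rows[[g]] <- data.frame(population = g, r, stringsAsFactors = FALSE)
    }
  rt <- .divOne(mk)
  rows[["Total"]] <- data.frame(population = "Total", rt, stringsAsFactors = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "retainedSites") <- length(keep)
  out
}

#' Uncorrected p-distance matrix
#'
#' Proportion of differing sites per sequence pair, computed with
#' [ape::dist.dna] (`model = "raw"`).  Under pairwise deletion each pair
#' uses the sites where both sequences are unambiguous; under complete
#' deletion only sites unambiguous across the whole sample are used.  Pairs
#' with no comparable site are returned as `NA` with a warning.
#'
#' @param aln A [PopAlignment-class].
#' @param deletion `"pairwise"` (default) or `"complete"`.
#' @return A symmetric numeric matrix with zero diagonal and attribute
#'   `deletion`.
#' @export
pDistanceMatrix <- function(aln, deletion = c("pairwise", "complete")) {
  deletion <- match.arg(deletion)
  m <- .alnCharMatrix(aln)
  if (ncol(m) < 1L) stop("alignment has no sites")
  db <- ape::as.DNAbin(m)
  d <- ape::dist.dna(db, model = "raw",
                     pairwise.deletion = (deletion == "pairwise"))
  D <- as.matrix(d)
  if (any(!is.finite(D))) {
    warning("sequence pair(s) with zero comparable sites: distance set to NA")
    D[!is.finite(D)] <- NA_real_
  }
  diag(D) <- 0
  attr(D, "deletion") <- deletion
  D
}

#' Pairwise nucleotide-difference counts
#'
#' Counts of differing sites per pair (the distance used by the haplotypic
#' AMOVA), under the same deletion modes as [pDistanceMatrix()].
#'
#' @inheritParams pDistanceMatrix
#' @param deletion `"complete"` (default, matching the AMOVA convention) or
#'   `"pairwise"`.
#' @return Symmetric integer-valued matrix of difference counts.
#' @export
pairwiseDifferenceMatrix <- function(aln, deletion = c("complete", "pairwise")) {
  deletion <- match.arg(deletion)
  m <- .alnCharMatrix(aln)
  if (deletion == "complete") {
    mk <- m[, .retainedSites(m), drop = FALSE]
    D <- .pairDiffCounts(mk)
  } else {
    n <- nrow(m)
    ok <- matrix(m %in% BASES, nrow = n)
    D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
    if (n >= 2L)
      for (i in seq_len(n - 1L))
        for (j in (i + 1L):n) {
          use <- ok[i, ] & ok[j, ]
          d <- sum(m[i, use] != m[j, use])
          D[i, j] <- d; D[j, i] <- d
        }
  }
  attr(D, "deletion") <- deletion
  D
}

#' Intra/inter-group partition of a distance matrix (barcoding gap)
#'
#' Assigns every off-diagonal pair to the intra- or inter-group set, returns
#' the group-pair mean distances and frequency-histogram counts on a common
#' set of bins, as used for barcoding-gap inspection.
#'
#' @param dm Symmetric distance matrix (e.g. from [pDistanceMatrix()]).
#' @param populations Group label per row of `dm` (factor or character),
#'   or a [PopAlignment-class] from which labels are taken.
#' @param bins Number of histogram bins.
#' @return A list with `intra`, `inter` (numeric vectors), `groupMeans`
#'   (matrix: diagonal = within-group means), `breaks`, `intraCounts`,
#'   `interCounts`.
#' @export
distancePartition <- function(dm, populations, bins = 20L) {
  if (is(populations, "PopAlignment")) populations <- populations(populations)
  pop <- as.character(populations)
  stopifnot(length(pop) == nrow(dm))
  groups <- unique(pop)
  ut <- which(upper.tri(dm), arr.ind = TRUE)
  same <- pop[ut[, 1L]] == pop[ut[, 2L]]
  vals <- dm[upper.tri(dm)]
  intra <- vals[same]
  inter <- vals[!same]
  G <- length(groups)
  gm <- matrix(NA_real_, G, G, dimnames = list(groups, groups))
  for (a in seq_len(G))
    for (b in a:G) {
      ia <- pop == groups[a]; ib <- pop == groups[b]
      if (a == b) {
        sub <- dm[ia, ia, drop = FALSE]
        gm[a, a] <- if (sum(ia) >= 2L) mean(sub[upper.tri(sub)], na.rm = TRUE) else NA_real_
      } else {
        gm[a, b] <- gm[b, a] <- mean(dm[ia, ib], na.rm = TRUE)
      }
    }
  hi <- max(c(intra, inter, 0), na.rm = TRUE)
  breaks <- seq(0, hi + max(hi, 1e-12) * 1e-8, length.out = bins + 1L)
  cint <- if (length(intra)) hist(intra, breaks = breaks, plot = FALSE)$counts else integer(bins)
  cinr <- if (length(inter)) hist(inter, breaks = breaks, plot = FALSE)$counts else integer(bins)
  list(intra = intra, inter = inter, groupMeans = gm, breaks = breaks,
       intraCounts = cint, interCounts = cinr)
}

#' Base composition
#'
#' Percentage of A, C, G and T over the unambiguous bases of the alignment
#' (gaps and ambiguity codes excluded from the denominator).
#'
#' @param aln A [PopAlignment-class].
#' @return Named numeric vector summing to 100.
#' @export
baseComposition <- function(aln) {
  m <- .alnCharMatrix(aln)
  counts <- vapply(BASES, function(b) sum(m == b), numeric(1))
  tot <- sum(counts)
  if (tot == 0) stop("alignment contains no unambiguous bases")
  100 * counts / tot
}

#' Theta estimators and conversion to effective size
#'
#' Watterson's estimator `theta_W = S / (a_{n-1} * L)` with
#' `a_{n-1} = sum(1/i, i = 1..n-1)`, or the pi estimator (per-site
#' nucleotide diversity), converted to effective population size through the
#' maternally inherited mtDNA relation `theta = Ne * mu`.
#'
#' @param aln Optional [PopAlignment-class]; if supplied, `S`, `n`, `L`
#'   (retained sites) and `pi` are computed from it.
#' @param S,n,L Segregating sites, sample size, sites (Watterson route).
#' @param pi Per-site nucleotide diversity (pi route).
#' @param mu Per-site per-generation mutation rate (> 0).
#' @param estimator `"watterson"` or `"pi"`.
#' @return A list of class `"ThetaEstimate"`: `theta` (per site), `Ne`,
#'   `mu`, `estimator`.
#' @examples
#' thetaNe(S = 0, n = 10, L = 100, mu = 3.9e-8)          # theta = Ne = 0
#' thetaNe(pi = 3.9e-3, mu = 3.9e-8, estimator = "pi")   # Ne = 1e5
#' @export
thetaNe <- function(aln = NULL, S = NULL, n = NULL, L = NULL, pi = NULL,
                    mu, estimator = c("watterson", "pi")) {
  estimator <- match.arg(estimator)
  if (!is.numeric(mu) || mu <= 0) stop("mu must be > 0")
  if (!is.null(aln)) {
    ds <- diversitySummary(aln, byPopulation = FALSE)
    S <- ds$S[ds$population == "Total"]
    n <- ds$n[ds$population == "Total"]
    L <- attr(ds, "retainedSites")
    pi <- ds$pi[ds$population == "Total"]
  }
  if (estimator == "watterson") {
    if (is.null(S) || is.null(n) || is.null(L)) stop("need S, n and L")
    if (n < 2) stop("n must be >= 2")
    a <- sum(1 / seq_len(n - 1L))
    theta <- S / (a * L)
  } else {
    if (is.null(pi)) stop("need pi")
    theta <- pi
  }
  structure(list(theta = theta, Ne = theta / mu, mu = mu,
                 estimator = estimator), class = "ThetaEstimate")
}

#' @export
print.ThetaEstimate <- function(x, ...) {
  cat("theta (", x$estimator, ", per site) = ", format(x$theta),
      ";  Ne = theta/mu = ", format(x$Ne), "\n", sep = "")
  invisible(x)
}

#' Convert a per-Myr substitution rate to a per-generation rate
#'
#' `rate per site per Myr * generation time (years) / 1e6`.
#'
#' @param ratePerSitePerMyr Substitution rate per site per million years.
#' @param generationTimeYears Generation time in years.
#' @return Per-site per-generation mutation rate.
#' @examples
#' substitutionRatePerGeneration(0.01306, 3)   # ~3.9e-8
#' @export
substitutionRatePerGeneration <- function(ratePerSitePerMyr, generationTimeYears) {
  ratePerSitePerMyr * generationTimeYears / 1e6
}
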