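# One-level Excoffier-Smouse-Quattro AMOVA on squared inter-haplotype
# distances.  With the default "number of pairwise nucleotide differences"
# distance the supplied values are the squared Euclidean distances delta^2
# between haplotypes, as in Arlequin's haplotypic AMOVA.

.amovaComponents <- function(d2, popIdx, nvec) {
  N <- nrow(d2)
  G <- length(nvec)
  ssTotal <- sum(d2[upper.tri(d2)]) / N
  ssWithin <- 0
  for (g in seq_len(G)) {
    idx <- which(popIdx == g)
    if (length(idx) >= 2L) {
      sub <- d2[idx, idx, drop = FALSE]
      ssWithin <- ssWithin + sum(sub[upper.tri(sub)]) / length(idx)
    }
  }
  ssAmong <- ssTotal - ssWithin
  dfAmong <- G - 1L
  dfWithin <- N - G
  msWithin <- if (dfWithin > 0L) ssWithin / dfWithin else 0
  msAmong <- if (dfAmong > 0L) ssAmong / dfAmong else 0
  nprime <- (N - sum(nvec^2) / N) / (G - 1L)
  s2w <- msWithin
  s2a <- if (nprime > 0) (msAmong - msWithin) / nprime else 0
  phi <- if ((s2a + s2w) > 0) s2a / (s2a + s2w) else 0
  list(ssAmong = ssAmong, ssWithin = ssWithin, dfAmong = dfAmong,
       dfWithin = dfWithin, sigma2Among = s2a, sigma2Within = s2w, phi = phi)
}

#' One-level analysis of molecular variance (AMOVA)
#'
#' Decomposes the squared pairwise distances among haplotypes into among-
#' and within-group variance components (Excoffier-Smouse-Quattro), reports
#' the fixation index `Phi_ST = sigma2_among / (sigma2_among + sigma2_within)`
#' and a permutation p-value obtained by shuffling individuals among groups.
#' The p-value uses the add-one correction
#' `(1 + #permuted >= observed) / (1 + nPerm)`.  Negative variance
#' components are reported as estimated; only the percentage of variation
#' clamps them to zero.
#'
#' @param dm Either a [PopAlignment-class] (distances are then the counts of
#'   pairwise nucleotide differences under complete deletion) or a symmetric
#'   matrix of squared distances.
#' @param populations Group labels per row (ignored when `dm` is a
#'   `PopAlignment`).
#' @param nPerm Number of permutations (`0` skips the test).
#' @param seed Optional integer seed, recorded in the result.
#' @return A list of class `"AmovaResult"`: sums of squares, degrees of
#'   freedom, variance components, `pctAmong`, `phiST`, `pValue`, `nPerm`,
#'   `seed`, `degenerate`.
#' @examples
#' aln <- PopAlignment(c(a = "AAAA", b = "AAAA", c = "TTTT", d = "TTTT"),
#'                     c("x", "x", "y", "y"))
#' amovaOneLevel(aln, nPerm = 99, seed = 1)$phiST   # 1: maximal structure
#' @export
amovaOneLevel <- function(dm, populations = NULL, nPerm = 10000L, seed = NULL) {
  if (is(dm, "PopAlignment")) {
    populations <- populations(dm)
    dm <- pairwiseDifferenceMatrix(dm, deletion = "complete")
  }
  if (is.null(populations)) stop("populations required")
  if (any(dm < 0, na.rm = TRUE)) stop("negative distances")
  if (nPerm < 0) stop("nPerm must be >= 0")
  pop <- factor(as.character(populations))
  if (nlevels(pop) < 2L) stop("AMOVA needs at least two groups")
  if (length(pop) != nrow(dm)) stop("labels must match the distance matrix")
  popIdx <- as.integer(pop)
  nvec <- as.numeric(table(popIdx))
  comp <- .amovaComponents(dm, popIdx, nvec)
  degenerate <- comp$sigma2Among == 0 && comp$sigma2Within == 0
  s2aPos <- max(comp$sigma2Among, 0)
  pct <- if ((s2aPos + comp$sigma2Within) > 0)
    100 * s2aPos / (s2aPos + comp$sigma2Within) else 0
  pValue <- NULL
  if (nPerm > 0L) {
    if (!is.null(seed)) set.seed(seed)
    ge <- 0L
    for (b in seq_len(nPerm)) {
      perm <- sample(popIdx)
      if (.amovaComponents(dm, perm, nvec)$phi >= comp$phi) ge <- ge + 1L
    }
    pValue <- (1 + ge) / (1 + nPerm)
  }
  structure(c(comp[c("ssAmong", "ssWithin", "dfAmong", "dfWithin",
                     "sigma2Among", "sigma2Within")],
              list(pctAmong = pct, phiST = comp$phi, pValue = pValue,
                   nPerm = as.integer(nPerm), seed = seed,
                   degenerate = degenerate)),
            class = "AmovaResult")
}

#' @export
print.AmovaResult <- function(x, ...) {
  cat("One-level AMOVA\n")
  cat(sprintf("  among groups:  SS = %.4f, df = %d, sigma2 = %.4f\n",
              x$ssAmong, x$dfAmong, x$sigma2Among))
  cat(sprintf("  within groups: SS = %.4f, df = %d, sigma2 = %.4f\n",
              x$ssWithin, x$dfWithin, x$sigma2Within))
  cat(sprintf("  %% variation among groups: %.2f\n", x$pctAmong))
  cat(sprintf("  Phi_ST = %.4f", x$phiST))
  if (!is.null(x$pValue))
    cat(sprintf("  (p = %.4g, %d permutations)", x$pValue, x$nPerm))
  cat("\n")
  if (x$degenerate) cat("  [degenerate: no molecular variance]\n")
  invisible(x)
}

#' Pairwise Phi_ST between groups
#'
#' Runs [amovaOneLevel()] on every pair of groups.
#'
#' @inheritParams amovaOneLevel
#' @return A list with matrices `phiST` and `pValue` (the latter `NULL`
#'   when `nPerm = 0`).
#' @export
pairwisePhiST <- function(dm, populations = NULL, nPerm = 10000L, seed = NULL) {
  if (is(dm, "PopAlignment")) {
    populations <- populations(dm)
    dm <- pairwiseDifferenceMatrix(dm, deletion = "complete")
  }
  pop <- factor(as.character(populations))
  if (nlevels(pop) < 2L) stop("need at least two groups")
  G <- nlevels(pop)
  labs <- levels(pop)
  phi <- matrix(NA_real_, G, G, dimnames = list(labs, labs))
  pv <- matrix(NA_real_, G, G, dimnames = list(labs, labs))
  diag(phi) <- 0
  if (!is.null(seed)) set.seed(seed)
  for (a in seq_len(G - 1L))
    for (b in (a + 1L):G) {
      idx <- which(pop %in% labs[c(a, b)])
      res <- amovaOneLevel(dm[idx, idx, drop = FALSE], pop[idx],
                           nPerm = nPerm, seed = NULL)
      phi[a, b] <- phi[b, a] <- res$phiST
      if (!is.null(res$pValue)) pv[a, b] <- pv[b, a] <- res$pValue
    }
  list(phiST = phi, pValue = if (nPerm > 0L) pv else NULL,
       nPerm = as.integer(nPerm), seed = seed)
}
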