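# Brute-force oracles: every implementation-facing quantity is recomputed
# here by direct enumeration of its definition, independently of the
# package's vectorized / C++ code paths.

BASES4 <- c("A", "C", "G", "T")

makeAln <- function(strings, pops) {
  if (is.null(names(strings)))
    names(strings) <- paste0("s", seq_along(strings))
  PopAlignment(strings, pops)
}

# random alignment as a character matrix; optional gaps/Ns
randomAlnMatrix <- function(n, L, pMiss = 0, nHapSeed = 2L) {
  anc <- sample(BASES4, L, replace = TRUE)
  m <- matrix(rep(anc, each = n), nrow = n)
  # sprinkle mutations so that variable, singleton and shared states occur
  nmut <- rpois(1, L / 3) + nHapSeed
  for (k in seq_len(nmut)) {
    s <- sample.int(L, 1)
    rows <- sample.int(n, sample.int(max(n - 1, 1), 1))
    m[rows, s] <- sample(setdiff(BASES4, m[rows[1], s]), 1)
  }
  if (pMiss > 0) {
    idx <- which(runif(length(m)) < pMiss)
    m[idx] <- sample(c("-", "N"), length(idx), replace = TRUE)
  }
  rownames(m) <- paste0("s", seq_len(n))
  m
}

matToAln <- function(m, pops = rep("p", nrow(m))) {
  strings <- apply(m, 1, paste, collapse = "")
  PopAlignment(strings, pops)
}

completeCols <- function(m) {
  which(apply(m, 2, function(col) all(col %in% BASES4)))
}

oracleDiversity <- function(m) {
  mk <- m[, completeCols(m), drop = FALSE]
  n <- nrow(mk)
  Lr <- ncol(mk)
  S <- 0L
  for (s in seq_len(Lr)) if (length(unique(mk[, s])) > 1L) S <- S + 1L
  tot <- 0; cnt <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    tot <- tot + sum(mk[i, ] != mk[j, ]); cnt <- cnt + 1
  }
  pi <- if (Lr > 0) (tot / cnt) / Lr else 0
  haps <- unique(apply(mk, 1, paste, collapse = ""))
  f <- table(factor(apply(mk, 1, paste, collapse = ""), levels = haps)) / n
  h <- n / (n - 1) * (1 - sum(f^2))
  list(n = n, p = length(haps), S = S, pi = pi, h = h)
}

oraclePdist <- function(m, pairwise = TRUE) {
  n <- nrow(m)
  D <- matrix(0, n, n)
  cols <- if (pairwise) NULL else completeCols(m)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (pairwise) {
      use <- m[i, ] %in% BASES4 & m[j, ] %in% BASES4
    } else {
      use <- seq_len(ncol(m)) %in% cols
    }
    D[i, j] <- if (sum(use) > 0) sum(m[i, use] != m[j, use]) / sum(use) else NA
  }
  D
}

# summary statistics by direct enumeration (complete deletion)
oracleSumstats <- function(m, pops) {
  mk <- m[, completeCols(m), drop = FALSE]
  n <- nrow(mk)
  lev <- if (is.factor(pops)) levels(pops) else unique(as.character(pops))
  pops <- as.character(pops)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    if (i != j) D[i, j] <- sum(mk[i, ] != mk[j, ])
  varSites <- which(apply(mk, 2, function(col) length(unique(col)) > 1))
  out <- c()
  mpdByPop <- setNames(numeric(length(lev)), lev)
  for (g in lev) {
    rows <- which(pops == g)
    haps <- unique(apply(mk[rows, , drop = FALSE], 1, paste, collapse = ""))
    seg <- sum(vapply(varSites, function(s)
      length(unique(mk[rows, s])) > 1, logical(1)))
    tot <- 0; cnt <- 0
    for (i in rows) for (j in rows) if (i < j) { tot <- tot + D[i, j]; cnt <- cnt + 1 }
    mpd <- if (cnt > 0) tot / cnt else 0
    mpdByPop[g] <- mpd
    priv <- 0
    for (s in varSites) {
      tab <- table(mk[, s])
      maj <- names(tab)[which.max(tab)]
      carriers <- which(mk[, s] != maj)
      if (length(unique(pops[carriers])) == 1 && all(pops[carriers] == g))
        priv <- priv + 1
    }
    out <- c(out, setNames(c(length(haps), seg, mpd, priv),
                           paste(c("nhap", "segsites", "mpd", "private"), g, sep = "_")))
  }
  for (a in seq_along(lev)) for (b in seq_along(lev)) {
    if (b <= a) next
    ra <- which(pops == lev[a]); rb <- which(pops == lev[b])
    tot <- 0
    for (i in ra) for (j in rb) tot <- tot + D[i, j]
    dxy <- tot / (length(ra) * length(rb))
    dw <- 0.5 * (mpdByPop[lev[a]] + mpdByPop[lev[b]])
    fst <- if (dxy > 0) 1 - dw / dxy else 0
    out <- c(out, setNames(c(dxy, fst),
                           c(paste("dxy", lev[a], lev[b], sep = "_"),
                             paste("fst", lev[a], lev[b], sep = "_"))))
  }
  out
}

# literal sums of the one-level variance decomposition
oracleAmova <- function(d2, pops) {
  pops <- as.character(pops)
  N <- nrow(d2)
  lev <- unique(pops)
  G <- length(lev)
  sst <- 0
  for (i in seq_len(N - 1)) for (j in (i + 1):N) sst <- sst + d2[i, j]
  sst <- sst / N
  ssw <- 0
  for (g in lev) {
    rows <- which(pops == g)
    sg <- 0
    for (i in rows) for (j in rows) if (i < j) sg <- sg + d2[i, j]
    ssw <- ssw + sg / length(rows)
  }
  ssa <- sst - ssw
  nvec <- as.numeric(table(factor(pops, levels = lev)))
  msw <- ssw / (N - G)
  msa <- ssa / (G - 1)
  nprime <- (N - sum(nvec^2) / N) / (G - 1)
  s2a <- (msa - msw) / nprime
  s2w <- msw
  list(ssAmong = ssa, ssWithin = ssw, sigma2Among = s2a, sigma2Within = s2w,
       phi = if (s2a + s2w > 0) s2a / (s2a + s2w) else 0)
}

# Monte-Carlo estimate of the probability that all sites carry <= 1
# mutation, conditional on j differing sites, under the same Poisson/JC
# per-site model (per-site conditional probabilities estimated by
# simulation of the mutation chain, then combined over sites)
mcParsimonyProbability <- function(j, L, nrep = 2e5) {
  lambda <- -0.75 * log(1 - 4 * j / (3 * L))
  k <- rpois(nrep, lambda)
  differs <- vapply(k, function(kk) {
    state <- 0L
    if (kk > 0) for (q in seq_len(kk)) state <- (state + sample.int(3, 1)) %% 4L
    state != 0L
  }, logical(1))
  qd <- mean(k[differs] <= 1)          # P(K <= 1 | endpoint differs)
  qs <- mean(k[!differs] <= 1)         # P(K <= 1 | endpoint same)
  qd^j * qs^(L - j)
}
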