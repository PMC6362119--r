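# DIYABC-style approximate Bayesian computation: summary statistics,
# reference table, model choice (direct rejection / weighted multinomial
# logistic regression), Beaumont local-linear parameter adjustment, and
# pseudo-observed-dataset (PODs) error validation.

#' Names of the summary-statistic vector
#'
#' Fixed ordering: for each population `nhap`, `segsites`, `mpd` (mean
#' pairwise differences) and `private` (private segregating sites), then
#' for each ordered population pair `dxy` (mean between-sample pairwise
#' differences) and `fst` (Hudson's estimator,
#' `1 - mean within-pair diversity / between-pair diversity`).
#'
#' @param popLabels Population labels in order.
#' @return Character vector of statistic names.
#' @export
statNames <- function(popLabels) {
  per <- as.vector(vapply(popLabels, function(p)
    paste(c("nhap", "segsites", "mpd", "private"), p, sep = "_"),
    character(4)))
  P <- length(popLabels)
  pair <- character(0)
  for (a in seq_len(P))
    for (b in seq_len(P))
      if (b > a)
        pair <- c(pair, paste("dxy", popLabels[a], popLabels[b], sep = "_"),
                  paste("fst", popLabels[a], popLabels[b], sep = "_"))
  c(per, pair)
}

#' Summary statistics of an alignment with populations
#'
#' Computes the DIYABC-style statistic vector (see [statNames()]) on the
#' sites retained under complete deletion.  A segregating site is private
#' to population `k` iff it is variable in the pooled sample and every
#' carrier of a non-major allele belongs to `k`.  Degenerate cases (no
#' variation) return zeros, including the FST entries.
#'
#' @param aln A [PopAlignment-class]; every population level must be
#'   sampled.
#' @return Named numeric vector in the fixed order.
#' @examples
#' aln <- PopAlignment(c(a = "AAAA", b = "AAAA", c = "TTTT", d = "TTTT"),
#'                     c("x", "x", "y", "y"))
#' computeSumstats(aln)[["fst_x_y"]]   # 1: maximal differentiation
#' @export
computeSumstats <- function(aln) {
  pop <- populations(aln)
  if (any(table(pop) == 0L)) stop("empty population level")
  m <- .alnCharMatrix(aln)
  keep <- .retainedSites(m)
  mk <- m[, keep, drop = FALSE]
  code <- matrix(match(mk, BASES) - 1L, nrow = nrow(mk))
  im <- t(code)                                # sites x individuals
  storage.mode(im) <- "integer"
  st <- .seq_stats_cpp(im, as.integer(pop) - 1L, nlevels(pop))
  names(st) <- statNames(levels(pop))
  st
}

#' Build an ABC reference table
#'
#' Simulates `nPerScenario` datasets per scenario with parameters drawn
#' from the prior, computes the summary statistics of each, and stores the
#' per-statistic robust standardization constants (median and MAD) computed
#' from the table itself.  Statistics with zero MAD are flagged and
#' excluded from rejection distances.
#'
#' @param scenarios List of [DemographicScenario-class] objects (e.g.
#'   [scenarioLibrary()]).
#' @param prior A [PriorSpec-class].
#' @param config A [SampleConfig-class].
#' @param nPerScenario Simulations per scenario.
#' @param seed Optional integer seed; with the same seed the table is
#'   reproduced exactly.
#' @return A [ReferenceTable-class].
#' @export
buildReferenceTable <- function(scenarios, prior, config, nPerScenario,
                                seed = NULL) {
  stopifnot(nPerScenario >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (prior@timesAreUpperBounds)
    stop("the batch simulator uses fixed divergence times; ",
         "draw times per dataset with simulateDataset() instead")
  popLabels <- scenarios[[1]]@popLabels
  paramNames <- names(prior@neLower)
  statsList <- list()
  paramsList <- list()
  scnIds <- vapply(scenarios, function(s) s@scenarioId, character(1))
  for (s in seq_along(scenarios)) {
    scn <- scenarios[[s]]
    stopifnot(identical(scn@popLabels, popLabels))
    ev <- .eventMatrix(scn, prior@times, paramIndex = TRUE,
                       paramNames = paramNames)
    res <- .sim_stats_batch_cpp(as.integer(nPerScenario),
                                config@sampleSizes, ev,
                                prior@neLower, prior@neUpper,
                                as.integer(config@L), config@mu)
    paramsList[[s]] <- res$params
    statsList[[s]] <- res$stats
  }
  stats <- do.call(rbind, statsList)
  params <- do.call(rbind, paramsList)
  colnames(stats) <- statNames(popLabels)
  colnames(params) <- paramNames
  scenario <- factor(rep(scnIds, each = nPerScenario), levels = scnIds)
  center <- apply(stats, 2L, median)
  scale <- apply(stats, 2L, mad)
  dropped <- colnames(stats)[scale == 0]
  if (length(dropped))
    warning("statistic(s) with zero MAD dropped from distances: ",
            paste(dropped, collapse = ", "))
  new("ReferenceTable", scenario = scenario, params = params, stats = stats,
      center = center, scale = scale, dropped = dropped,
      priorLower = prior@neLower, priorUpper = prior@neUpper,
      seed = if (is.null(seed)) NA_real_ else as.numeric(seed))
}

# standardized statistics (kept columns only); x may be a matrix or vector
.standardize <- function(rt, x) {
  keep <- setdiff(colnames(rt@stats), rt@dropped)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L, dimnames = list(NULL, names(x)))
  sweep(sweep(x[, keep, drop = FALSE], 2L, rt@center[keep]), 2L,
        rt@scale[keep], "/")
}

.obsStats <- function(obs) {
  if (is(obs, "PopAlignment")) computeSumstats(obs) else obs
}

#' ABC model choice by direct rejection
#'
#' Standardizes all statistics by the reference table's median/MAD, finds
#' the `k` rows closest to the observed vector in Euclidean distance, and
#' returns the scenario proportions among them as posterior probabilities.
#'
#' @param rt A [ReferenceTable-class].
#' @param obs Observed statistics (named vector) or a
#'   [PopAlignment-class].
#' @param k Acceptance size (default 500).
#' @return A list of class `"ModelPosterior"`: `posterior` (named, sums to
#'   1), `method = "direct"`, `k`, `best`.
#' @export
modelChoiceDirect <- function(rt, obs, k = 500L) {
  if (k <= 0) stop("k must be positive")
  if (k > length(rt)) stop("k exceeds the reference-table size")
  obs <- .obsStats(obs)
  Z <- .standardize(rt, rt@stats)
  zo <- .standardize(rt, obs)
  d2 <- colSums((t(Z) - as.numeric(zo))^2)
  kth <- sort(d2, partial = k)[k]
  accIdx <- which(d2 <= kth)
  if (length(accIdx) > k)
    warning("distance ties at the k-th neighbour: accepting all ",
            length(accIdx), " tied rows")
  acc <- rt@scenario[accIdx]
  post <- as.numeric(table(acc)) / length(acc)
  names(post) <- levels(rt@scenario)
  structure(list(posterior = post, method = "direct", k = as.integer(k),
                 best = names(post)[which.max(post)]),
            class = "ModelPosterior")
}

#' ABC model choice by weighted multinomial logistic regression
#'
#' Fits a multinomial logistic regression of the scenario indicator on the
#' standardized statistics (centred at the observed vector) over the
#' closest `frac` of the reference table, with Epanechnikov distance-kernel
#' weights, and evaluates the fitted probabilities at the observed point.
#' If the accepted set contains a single scenario the method falls back to
#' direct rejection with a warning; a failed fit is retried with a small
#' ridge penalty (`decay`).
#'
#' @inheritParams modelChoiceDirect
#' @param frac Fraction of closest rows to accept (default 0.01).
#' @return A list of class `"ModelPosterior"` (`method = "logistic"`).
#' @export
modelChoiceLogistic <- function(rt, obs, frac = 0.01) {
  if (frac <= 0 || frac > 1) stop("frac must be in (0, 1]")
  obs <- .obsStats(obs)
  Z <- .standardize(rt, rt@stats)
  zo <- as.numeric(.standardize(rt, obs))
  d2 <- colSums((t(Z) - zo)^2)
  nacc <- max(2L, ceiling(frac * length(d2)))
  ord <- order(d2)[seq_len(nacc)]
  y <- droplevels(rt@scenario[ord])
  if (nlevels(y) < 2L) {
    warning("accepted set contains a single scenario; falling back to direct rejection")
    res <- modelChoiceDirect(rt, obs, k = nacc)
    res$method <- "logistic(fallback-direct)"
    return(res)
  }
  X <- sweep(Z[ord, , drop = FALSE], 2L, zo)
  d <- sqrt(d2[ord])
  dmax <- max(d)
  w <- if (dmax > 0) 1 - (d / dmax)^2 else rep(1, length(d))
  w[w <= 0] <- min(w[w > 0], 1e-8)
  keepCol <- apply(X, 2L, function(v) stats::sd(v) > 0)
  dat <- data.frame(.y = y, X[, keepCol, drop = FALSE])
  fit <- tryCatch(
    nnet::multinom(.y ~ ., data = dat, weights = w, trace = FALSE,
                   maxit = 500, MaxNWts = 5000),
    error = function(e) NULL)
  if (is.null(fit)) {
    warning("singular multinomial fit; refitting with ridge penalty")
    fit <- nnet::multinom(.y ~ ., data = dat, weights = w, trace = FALSE,
                          maxit = 500, MaxNWts = 5000, decay = 0.01)
  }
  nd <- as.data.frame(matrix(0, 1L, sum(keepCol)))
  names(nd) <- names(dat)[-1L]
  pr <- predict(fit, newdata = nd, type = "probs")
  if (nlevels(y) == 2L) pr <- c(1 - pr, pr)   # multinom returns P(level 2)
  names(pr) <- levels(y)
  post <- stats::setNames(numeric(nlevels(rt@scenario)), levels(rt@scenario))
  post[names(pr)] <- pr
  post <- post / sum(post)
  structure(list(posterior = post, method = "logistic",
                 frac = frac, nAccepted = nacc,
                 best = names(post)[which.max(post)]),
            class = "ModelPosterior")
}

#' @export
print.ModelPosterior <- function(x, ...) {
  cat("ABC model choice (", x$method, "):\n", sep = "")
  for (s in names(x$posterior))
    cat(sprintf("  %-18s Pp = %.3f%s\n", s, x$posterior[s],
                if (s == x$best) "  <- best" else ""))
  invisible(x)
}

#' Local-linear-regression parameter posteriors (Beaumont adjustment)
#'
#' Restricts the reference table to one scenario, accepts the closest
#' `frac` of its rows, and adjusts each accepted parameter by a weighted
#' linear regression on the standardized statistics centred at the observed
#' vector: `theta* = theta_hat(s_obs) + residual`.  Parameters are
#' regressed on a logit transform of their prior range, so adjusted draws
#' always remain within the prior support.  Collinear statistics dropped by
#' the regression are reported with a warning.
#'
#' @inheritParams modelChoiceDirect
#' @param scenarioId Which scenario's rows to use (default: all rows'
#'   scenario levels must then be identical).
#' @param frac Fraction of closest rows to accept (default 0.01).
#' @return A list of class `"ParameterPosterior"`: per-parameter adjusted
#'   draws, Epanechnikov `weights`, weighted `median` and 95% credible
#'   interval.
#' @export
estimateParameters <- function(rt, obs, scenarioId = NULL, frac = 0.01) {
  obs <- .obsStats(obs)
  rows <- if (is.null(scenarioId)) seq_along(rt@scenario)
          else which(rt@scenario == scenarioId)
  if (!length(rows)) stop("no rows for scenario ", scenarioId)
  Z <- .standardize(rt, rt@stats[rows, , drop = FALSE])
  zo <- as.numeric(.standardize(rt, obs))
  d2 <- colSums((t(Z) - zo)^2)
  nacc <- ceiling(frac * length(d2))
  if (nacc < 50L) stop("fewer than 50 accepted rows; enlarge the table or frac")
  ord <- order(d2)[seq_len(nacc)]
  X <- sweep(Z[ord, , drop = FALSE], 2L, zo)
  d <- sqrt(d2[ord]); dmax <- max(d)
  w <- if (dmax > 0) 1 - (d / dmax)^2 else rep(1, length(d))
  w[w <= 0] <- min(w[w > 0], 1e-8)
  theta <- rt@params[rows, , drop = FALSE][ord, , drop = FALSE]
  Xd <- cbind(`(Intercept)` = 1, X)
  out <- list()
  droppedAny <- character(0)
  for (pn in colnames(theta)) {
    a <- rt@priorLower[[pn]]; b <- rt@priorUpper[[pn]]
    u <- pmin(pmax((theta[, pn] - a) / (b - a), 1e-6), 1 - 1e-6)
    yy <- qlogis(u)
    fit <- lm.wfit(Xd, yy, w)
    cf <- fit$coefficients
    dropped <- names(cf)[is.na(cf)]
    if (length(dropped)) droppedAny <- union(droppedAny, dropped)
    ystar <- cf[["(Intercept)"]] + fit$residuals
    draws <- a + (b - a) * plogis(ystar)
    qs <- .weightedQuantile(draws, w, c(0.025, 0.5, 0.975))
    out[[pn]] <- list(draws = unname(draws), median = qs[2L],
                      ci = c(lower = qs[1L], upper = qs[3L]))
  }
  if (length(droppedAny))
    warning("collinear statistic(s) dropped from the regression: ",
            paste(droppedAny, collapse = ", "))
  structure(list(parameters = out, weights = w, nAccepted = nacc,
                 scenarioId = scenarioId, frac = frac),
            class = "ParameterPosterior")
}

.weightedQuantile <- function(x, w, probs) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  vapply(probs, function(p) x[which(cw >= p)[1L]], numeric(1))
}

#' @export
print.ParameterPosterior <- function(x, ...) {
  cat("ABC parameter posteriors (", x$nAccepted, " accepted draws)\n", sep = "")
  for (pn in names(x$parameters)) {
    pp <- x$parameters[[pn]]
    cat(sprintf("  %-14s median %.4g  [%.4g, %.4g]\n", pn, pp$median,
                pp$ci[1L], pp$ci[2L]))
  }
  invisible(x)
}

# classify a matrix of POD statistic vectors by direct rejection
.directClassifyBatch <- function(rt, statsMat, k) {
  Zt <- t(.standardize(rt, rt@stats))            # stats x rows
  Zo <- .standardize(rt, statsMat)
  lev <- levels(rt@scenario)
  scn <- as.integer(rt@scenario)
  out <- integer(nrow(Zo))
  for (i in seq_len(nrow(Zo))) {
    d2 <- colSums((Zt - as.numeric(Zo[i, ]))^2)
    acc <- scn[d2 <= sort(d2, partial = k)[k]]
    tab <- tabulate(acc, nbins = length(lev))
    out[i] <- which.max(tab)
  }
  factor(lev[out], levels = lev)
}

#' Pseudo-observed-dataset (PODs) validation of ABC model choice
#'
#' Simulates `nPods` datasets from the prior predictive of every scenario,
#' classifies each with the chosen model-choice method against the given
#' reference table, and reports the confusion matrix together with the
#' focal scenario's error rates: type I (the focal scenario is true but not
#' selected) and type II (another scenario is true but the focal one is
#' selected, averaged over the non-focal scenarios).
#'
#' @inheritParams buildReferenceTable
#' @param rt The [ReferenceTable-class] to classify against.
#' @param focal Scenario id whose error rates are reported.
#' @param nPods PODs per scenario.
#' @param method `"direct"` (default) or `"logistic"`.
#' @param k,frac Acceptance sizes for the two methods.
#' @return A list of class `"ConfusionReport"`: `confusion` (true x
#'   selected counts), `typeI`, `typeII`, `nPods`, `focal`, `method`,
#'   `seed`.
#' @export
podsValidation <- function(scenarios, prior, config, rt, focal,
                           nPods = 1000L, method = c("direct", "logistic"),
                           k = 500L, frac = 0.01, seed = NULL) {
  method <- match.arg(method)
  stopifnot(nPods >= 1)
  if (!is.null(seed)) set.seed(seed)
  scnIds <- vapply(scenarios, function(s) s@scenarioId, character(1))
  if (!focal %in% scnIds) stop("focal scenario not among the scenarios")
  lev <- levels(rt@scenario)
  conf <- matrix(0L, length(scnIds), length(lev),
                 dimnames = list(true = scnIds, selected = lev))
  paramNames <- names(prior@neLower)
  for (s in seq_along(scenarios)) {
    scn <- scenarios[[s]]
    ev <- .eventMatrix(scn, prior@times, paramIndex = TRUE,
                       paramNames = paramNames)
    sim <- .sim_stats_batch_cpp(as.integer(nPods), config@sampleSizes, ev,
                                prior@neLower, prior@neUpper,
                                as.integer(config@L), config@mu)
    colnames(sim$stats) <- statNames(scn@popLabels)
    sel <- if (method == "direct") {
      .directClassifyBatch(rt, sim$stats, k)
    } else {
      factor(vapply(seq_len(nPods), function(i)
        suppressWarnings(
          modelChoiceLogistic(rt, sim$stats[i, ], frac = frac)$best),
        character(1)), levels = lev)
    }
    conf[s, ] <- as.integer(table(sel))
  }
  typeI <- 1 - conf[focal, focal] / nPods
  others <- setdiff(scnIds, focal)
  typeII <- mean(conf[others, focal] / nPods)
  structure(list(confusion = conf, typeI = typeI, typeII = typeII,
                 nPods = as.integer(nPods), focal = focal, method = method,
                 k = k, frac = frac, seed = seed),
            class = "ConfusionReport")
}

#' @export
print.ConfusionReport <- function(x, ...) {
  cat("PODs validation (", x$method, ", ", x$nPods, " PODs per scenario)\n",
      sep = "")
  print(x$confusion)
  cat(sprintf("focal scenario %s: type I = %.1f%%, type II = %.1f%%\n",
              x$focal, 100 * x$typeI, 100 * x$typeII))
  invisible(x)
}
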