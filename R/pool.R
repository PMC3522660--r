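## Pool design: pairwise compatibility, maximum pools, partitioning into
## fewest runs, and per-run capacity / cost.

#' Construct a compatibility policy
#'
#' @param coiThreshold minimum Folmer COI proxy divergence (default 0.15).
#' @param windowThreshold minimum per-window divergence (default 0.05).
#' @param windowLength the window length the window rule refers to
#'   (default 450 bp).
#' @param mode "proxy_only", "windows_only" or "windows_preferred" (use the
#'   window rule when a profile exists, else fall back to the proxy).
#' @return a [CompatPolicy-class].
#' @export
compatPolicy <- function(coiThreshold = 0.15, windowThreshold = 0.05,
                         windowLength = 450L,
                         mode = c("windows_preferred", "proxy_only",
                                  "windows_only")) {
  mode <- match.arg(mode)
  obj <- new("CompatPolicy", coiThreshold = coiThreshold,
             windowThreshold = windowThreshold,
             windowLength = as.integer(windowLength), mode = mode)
  validObject(obj)
  obj
}

#' Build the pairwise compatibility matrix for a specimen set
#'
#' A pair is compatible when its divergence evidence meets the policy:
#' Folmer proxy at or above `coiThreshold` (proxy modes), or minimum
#' informative 450 bp window divergence at or above `windowThreshold`
#' (window modes). Pairs lacking the required evidence are conservatively
#' incompatible and flagged "insufficient data".
#'
#' @param genomes list of [AnnotatedMitogenome-class] objects.
#' @param policy a [CompatPolicy-class].
#' @param profiles optional named list of [DivergenceProfile-class]
#'   objects, names `"idA|idB"`; computed on the fly from anchored
#'   alignments in window modes when missing and `computeProfiles = TRUE`.
#' @param computeProfiles align pairs and compute profiles when needed.
#' @return a [CompatibilityMatrix-class].
#' @export
buildCompatibility <- function(genomes, policy = compatPolicy(),
                               profiles = NULL, computeProfiles = TRUE) {
  if (length(genomes) < 2) stop("need at least 2 genomes")
  ids <- vapply(genomes, genomeId, character(1))
  if (anyDuplicated(ids)) stop("genome ids must be unique")
  n <- length(ids)
  proxy <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  minw <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  flags <- matrix("ok", n, n, dimnames = list(ids, ids))
  compat <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  profKey <- function(a, b) paste(a, b, sep = "|")
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    px <- tryCatch(suppressWarnings(folmerProxy(genomes[[i]], genomes[[j]])),
                   error = function(e) NA_real_)
    proxy[i, j] <- proxy[j, i] <- px
    mw <- NA_real_
    if (policy@mode != "proxy_only") {
      pr <- NULL
      if (!is.null(profiles))
        pr <- profiles[[profKey(ids[i], ids[j])]] %||%
              profiles[[profKey(ids[j], ids[i])]]
      if (is.null(pr) && computeProfiles) {
        pr <- tryCatch({
          aln <- alignAnchored(genomes[[i]], genomes[[j]])
          slidingProfile(aln, policy@windowLength,
                         max(1L, policy@windowLength %/% 10L))
        }, error = function(e) NULL)
      }
      if (!is.null(pr)) mw <- minWindowDivergence(pr)
    }
    minw[i, j] <- minw[j, i] <- mw
    ok <- switch(policy@mode,
      proxy_only = !is.na(px) && px >= policy@coiThreshold,
      windows_only = !is.na(mw) && mw >= policy@windowThreshold,
      windows_preferred =
        if (!is.na(mw)) mw >= policy@windowThreshold
        else !is.na(px) && px >= policy@coiThreshold)
    evid <- switch(policy@mode,
      proxy_only = px,
      windows_only = mw,
      windows_preferred = if (!is.na(mw)) mw else px)
    if (is.na(evid)) {
      flags[i, j] <- flags[j, i] <- "insufficient data"
      ok <- FALSE
    }
    compat[i, j] <- compat[j, i] <- isTRUE(ok)
  }
  obj <- new("CompatibilityMatrix", ids = ids, compatible = compat,
             coiProxy = proxy, minWindow = minw, flags = flags,
             policy = policy)
  validObject(obj)
  obj
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a compatibility matrix directly from evidence values
#'
#' Convenience constructor for precomputed proxies/window minima (e.g.
#' from external alignments), bypassing sequence work.
#'
#' @param ids specimen labels.
#' @param coiProxy,minWindow symmetric matrices (NA allowed).
#' @param policy a [CompatPolicy-class].
#' @return a [CompatibilityMatrix-class].
#' @export
compatibilityFromEvidence <- function(ids, coiProxy = NULL, minWindow = NULL,
                                      policy = compatPolicy()) {
  n <- length(ids)
  if (is.null(coiProxy)) coiProxy <- matrix(NA_real_, n, n)
  if (is.null(minWindow)) minWindow <- matrix(NA_real_, n, n)
  dimnames(coiProxy) <- dimnames(minWindow) <- list(ids, ids)
  compat <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  flags <- matrix("ok", n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    px <- coiProxy[i, j]; mw <- minWindow[i, j]
    ok <- switch(policy@mode,
      proxy_only = !is.na(px) && px >= policy@coiThreshold,
      windows_only = !is.na(mw) && mw >= policy@windowThreshold,
      windows_preferred =
        if (!is.na(mw)) mw >= policy@windowThreshold
        else !is.na(px) && px >= policy@coiThreshold)
    if (is.na(px) && is.na(mw)) flags[i, j] <- flags[j, i] <- "insufficient data"
    compat[i, j] <- compat[j, i] <- isTRUE(ok)
  }
  new("CompatibilityMatrix", ids = ids, compatible = compat,
      coiProxy = coiProxy, minWindow = minWindow, flags = flags,
      policy = policy)
}

## exact maximum clique by branch and bound with greedy colouring bound;
## returns the lexicographically smallest maximum clique (ids sorted)
.maxCliqueExact <- function(adj) {
  n <- nrow(adj)
  best <- integer(0)
  order0 <- order(-colSums(adj))
  expand <- function(clique, cand) {
    if (!length(cand)) {
      if (length(clique) > length(best) ||
          (length(clique) == length(best) &&
           .lexLess(sort(clique), sort(best)))) best <<- clique
      return(invisible())
    }
    if (length(clique) + length(cand) < length(best)) return(invisible())
    for (i in seq_along(cand)) {
      if (length(clique) + length(cand) - i + 1 < length(best)) break
      v <- cand[i]
      newCand <- cand[-seq_len(i)]
      newCand <- newCand[adj[v, newCand]]
      expand(c(clique, v), newCand)
    }
    invisible()
  }
  expand(integer(0), order0)
  sort(best)
}

.lexLess <- function(a, b) {
  if (!length(b)) return(TRUE)
  for (i in seq_len(min(length(a), length(b)))) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  length(a) < length(b)
}

## greedy construction + 1-swap local search, deterministic under seed
.maxCliqueGreedy <- function(adj, seed = 1L, restarts = 20L) {
  n <- nrow(adj)
  withr::with_seed(seed, {
    best <- integer(0)
    for (r in seq_len(restarts)) {
      ord <- sample.int(n)
      cl <- integer(0)
      for (v in ord) if (all(adj[v, cl])) cl <- c(cl, v)
      improved <- TRUE
      while (improved) {
        improved <- FALSE
        for (v in setdiff(seq_len(n), cl)) {
          conn <- sum(adj[v, cl])
          if (conn == length(cl)) {
            cl <- c(cl, v); improved <- TRUE
          } else if (conn == length(cl) - 1 && length(cl) >= 2) {
            drop <- cl[!adj[v, cl]]
            cand <- c(setdiff(cl, drop), v)
            extra <- which(apply(adj[, cand, drop = FALSE], 1,
                                 all) & !(seq_len(n) %in% cand))
            if (length(extra)) {
              cl <- c(cand, extra[1]); improved <- TRUE
            }
          }
        }
      }
      if (length(cl) > length(best) ||
          (length(cl) == length(best) && .lexLess(sort(cl), sort(best))))
        best <- cl
    }
    sort(best)
  })
}

#' Largest mutually compatible pool
#'
#' Finds a maximum clique in the compatibility graph: exact
#' branch-and-bound up to 25 specimens, greedy-plus-swap local search with
#' a fixed seed above. Ties are broken towards the lexicographically
#' smallest member list.
#'
#' @param matrix a [CompatibilityMatrix-class].
#' @param exactLimit exact search up to this many specimens (default 25).
#' @param seed seed for the heuristic used above `exactLimit`.
#' @return a [PoolPlan-class].
#' @export
maxPool <- function(matrix, exactLimit = 25L, seed = 1L) {
  adj <- matrix@compatible
  n <- nrow(adj)
  idx <- if (n <= exactLimit) .maxCliqueExact(adj) else .maxCliqueGreedy(adj, seed)
  if (!length(idx)) idx <- 1L          # a singleton pool is always feasible
  members <- sort(matrix@ids[idx])
  new("PoolPlan", members = members,
      minPairwise = .minEvidence(matrix, idx), policy = matrix@policy)
}

.minEvidence <- function(matrix, idx) {
  if (length(idx) < 2) return(NA_real_)
  ev <- if (matrix@policy@mode == "proxy_only") matrix@coiProxy
        else ifelse(is.na(matrix@minWindow), matrix@coiProxy, matrix@minWindow)
  sub <- ev[idx, idx]
  vals <- sub[upper.tri(sub)]
  if (all(is.na(vals))) NA_real_ else min(vals, na.rm = TRUE)
}

## DSATUR colouring of a graph given as logical adjacency; deterministic
.dsatur <- function(adj) {
  n <- nrow(adj)
  colour <- rep(NA_integer_, n)
  degree <- colSums(adj)
  for (step in seq_len(n)) {
    sat <- vapply(seq_len(n), function(v) {
      if (!is.na(colour[v])) return(-1L)
      length(unique(colour[adj[v, ] & !is.na(colour)]))
    }, integer(1))
    cand <- which(sat == max(sat))
    cand <- cand[order(-degree[cand], cand)]
    v <- cand[1]
    used <- unique(colour[adj[v, ] & !is.na(colour)])
    colour[v] <- setdiff(seq_len(n), used)[1]
  }
  colour
}

#' Partition a specimen set into the fewest internally compatible pools
#'
#' Colours the incompatibility graph with the DSATUR heuristic; each
#' colour class is a pool whose members are pairwise compatible. The
#' reported lower bound is the size of the largest clique of the
#' incompatibility graph (specimens that must all be separated).
#'
#' @param matrix a [CompatibilityMatrix-class].
#' @return list with `pools` (list of [PoolPlan-class]), `nPools`, and
#'   `lowerBound`.
#' @export
partitionPools <- function(matrix) {
  inc <- !matrix@compatible
  diag(inc) <- FALSE
  colour <- .dsatur(inc)
  pools <- lapply(sort(unique(colour)), function(cl) {
    idx <- which(colour == cl)
    new("PoolPlan", members = sort(matrix@ids[idx]),
        minPairwise = .minEvidence(matrix, idx), policy = matrix@policy)
  })
  lb <- length(.maxCliqueExact(inc))
  if (nrow(inc) > 25L) lb <- max(lb, 1L)
  list(pools = pools, nPools = length(pools), lowerBound = max(lb, 1L))
}

#' Sequencer throughput and run-cost presets
#'
#' Published minimum-throughput and run-cost figures for the bench-top
#' platforms the capacity table covers, with the coverage each cost
#' estimate refers to.
#'
#' @return data.frame with `platform`, `throughput_bp`, `run_cost`,
#'   `cost_coverage`.
#' @export
sequencerSpecs <- function() {
  data.frame(
    platform = c("454_gs_junior", "ion_torrent_314", "ion_torrent_316",
                 "ion_torrent_318", "illumina_miseq", "illumina_hiseq2000",
                 "illumina_hiseq2000_lane"),
    throughput_bp = c(35e6, 10e6, 100e6, 1e9, 1.5e9, 600e9, 40e9),
    run_cost = c(1100, 225, 425, 625, 750, 42000, 2800),
    cost_coverage = c(20, 50, 50, 50, 50, 100, 100),
    stringsAsFactors = FALSE)
}

#' Mitogenomes per sequencing run and cost per genome
#'
#' With an enrichment step yielding a library whose fraction
#' `mitoFraction` is mitochondrial and equimolar pooling, a run of
#' `throughput` bases sequences
#' `throughput * mitoFraction / (genomeLength * coverage)` complete
#' genomes at the requested mean coverage. The genome count is rounded
#' half-up; the cost per genome is the run cost divided by the unrounded
#' quotient, rounded to 2 decimals.
#'
#' @param throughput run throughput in bases.
#' @param coverage target mean coverage (x).
#' @param runCost cost of one run (currency units).
#' @param genomeLength average mitogenome length (default 17,000 bp).
#' @param mitoFraction mitochondrial fraction of the library (default 0.5).
#' @return list with `genomesPerRun`, `costPerGenome`, `raw`.
#' @export
runCapacity <- function(throughput, coverage, runCost = NA_real_,
                        genomeLength = 17000, mitoFraction = 0.5) {
  vals <- c(throughput = throughput, coverage = coverage,
            genomeLength = genomeLength, mitoFraction = mitoFraction)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("throughput, coverage, genomeLength and mitoFraction must be positive")
  raw <- throughput * mitoFraction / (genomeLength * coverage)
  genomes <- as.integer(floor(raw + 0.5))
  cost <- if (is.na(runCost)) NA_real_ else round(runCost / raw, 2)
  list(genomesPerRun = genomes, costPerGenome = cost, raw = raw)
}

#' Capacity table across the preset sequencers
#'
#' @param coverages coverages to tabulate (default 20, 50, 100).
#' @param genomeLength,mitoFraction see [runCapacity()].
#' @return data.frame with one row per platform: genome counts per
#'   coverage and the cost per genome at each platform's reference
#'   coverage.
#' @export
capacityTable <- function(coverages = c(20, 50, 100), genomeLength = 17000,
                          mitoFraction = 0.5) {
  specs <- sequencerSpecs()
  counts <- sapply(coverages, function(cv)
    vapply(seq_len(nrow(specs)), function(i)
      runCapacity(specs$throughput_bp[i], cv, genomeLength = genomeLength,
                  mitoFraction = mitoFraction)$genomesPerRun, integer(1)))
  colnames(counts) <- paste0("genomes_", coverages, "x")
  cost <- vapply(seq_len(nrow(specs)), function(i)
    runCapacity(specs$throughput_bp[i], specs$cost_coverage[i],
                specs$run_cost[i], genomeLength, mitoFraction)$costPerGenome,
    numeric(1))
  cbind(specs, as.data.frame(counts), cost_per_genome = cost)
}
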