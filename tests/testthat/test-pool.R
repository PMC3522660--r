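# Pool compatibility, maximum pools, partitioning and run capacity.

test_that("compatibility follows the policy thresholds", {
  ids <- c("a", "b", "c")
  proxy <- matrix(NA_real_, 3, 3)
  proxy[1, 2] <- proxy[2, 1] <- 0.16   # above the 15% rule
  proxy[1, 3] <- proxy[3, 1] <- 0.10   # below
  cm <- compatibilityFromEvidence(ids, coiProxy = proxy,
                                  policy = compatPolicy(mode = "proxy_only"))
  expect_true(cm@compatible["a", "b"])
  expect_false(cm@compatible["a", "c"])
  expect_false(cm@compatible["b", "c"])       # no evidence
  expect_equal(cm@flags["b", "c"], "insufficient data")
  expect_false(any(diag(cm@compatible)))

  mw <- matrix(NA_real_, 3, 3)
  mw[1, 2] <- mw[2, 1] <- 0.04                # a 450 bp window under 5%
  mw[1, 3] <- mw[3, 1] <- 0.06
  cmw <- compatibilityFromEvidence(ids, minWindow = mw,
                                   policy = compatPolicy(mode = "windows_only"))
  expect_false(cmw@compatible["a", "b"])
  expect_true(cmw@compatible["a", "c"])
})

test_that("buildCompatibility on genomes: self is incompatible, divergent pairs pool", {
  fam <- smallFamily()
  g <- fam$genomes[1:3]
  gg <- c(g, list(annotatedMitogenome("T01copy",
                                      as.character(genomeSeq(g[[1]])),
                                      genes = genes(g[[1]]))))
  cm <- buildCompatibility(gg, compatPolicy(mode = "proxy_only"))
  expect_true(all(cm@compatible[1:3, 1:3][upper.tri(diag(3))]))
  expect_false(cm@compatible["T01", "T01copy"])  # proxy 0 vs itself
  expect_equal(unname(cm@coiProxy["T01", "T01copy"]), 0)
})

test_that("maxPool matches the exhaustive clique oracle on random instances", {
  withr::with_seed(31, seeds <- sample.int(1e6, 40))
  for (i in seq_along(seeds)) {
    cm <- randomCompat(10, pEdge = 0.45, seed = seeds[i])
    mp <- maxPool(cm)
    expect_equal(length(poolMembers(mp)), oracleCliqueNum(cm@compatible))
    # every returned pair verifies the policy on recomputation
    mem <- match(poolMembers(mp), cm@ids)
    if (length(mem) > 1) {
      sub <- cm@compatible[mem, mem]
      expect_true(all(sub[upper.tri(sub)]))
    }
  }
})

test_that("maxPool breaks ties towards the lexicographically smallest pool", {
  # AB and BC compatible, AC not: {A,B} beats {B,C}
  proxy <- matrix(NA_real_, 3, 3, dimnames = NULL)
  proxy[1, 2] <- proxy[2, 1] <- 0.2
  proxy[2, 3] <- proxy[3, 2] <- 0.2
  proxy[1, 3] <- proxy[3, 1] <- 0.01
  cm <- compatibilityFromEvidence(c("A", "B", "C"), coiProxy = proxy,
                                  policy = compatPolicy(mode = "proxy_only"))
  expect_identical(poolMembers(maxPool(cm)), c("A", "B"))
})

test_that("fully compatible and fully incompatible sets are handled", {
  n <- 10
  proxy <- matrix(0.3, n, n); diag(proxy) <- NA
  cm <- compatibilityFromEvidence(sprintf("x%02d", 1:n), coiProxy = proxy,
                                  policy = compatPolicy(mode = "proxy_only"))
  expect_length(poolMembers(maxPool(cm)), n)
  expect_equal(partitionPools(cm)$nPools, 1)

  proxy0 <- matrix(0.01, 4, 4); diag(proxy0) <- NA
  cm0 <- compatibilityFromEvidence(letters[1:4], coiProxy = proxy0,
                                   policy = compatPolicy(mode = "proxy_only"))
  expect_length(poolMembers(maxPool(cm0)), 1)   # singleton always feasible
  expect_equal(partitionPools(cm0)$nPools, 4)
})

test_that("partitionPools stays within one colour of the exact chromatic number", {
  withr::with_seed(32, seeds <- sample.int(1e6, 30))
  gaps <- vapply(seeds, function(sd) {
    cm <- randomCompat(8, pEdge = 0.5, seed = sd)
    res <- partitionPools(cm)
    # pools are disjoint and cover every specimen
    members <- unlist(lapply(res$pools, poolMembers))
    expect_identical(sort(members), sort(cm@ids))
    # each pool internally compatible
    for (pl in res$pools) {
      idx <- match(poolMembers(pl), cm@ids)
      if (length(idx) > 1) {
        sub <- cm@compatible[idx, idx]
        expect_true(all(sub[upper.tri(sub)]))
      }
    }
    inc <- !cm@compatible; diag(inc) <- FALSE
    chi <- oracleChromatic(inc)
    expect_gte(res$lowerBound, 1)
    expect_lte(res$lowerBound, chi)
    res$nPools - chi
  }, numeric(1))
  expect_true(all(gaps <= 1))
  expect_gte(mean(gaps == 0), 0.9)
})

test_that("runCapacity reproduces the printed capacity table", {
  # genome counts at 20x / 50x / 100x for the seven platforms
  expected <- list(
    "454_gs_junior" = c(51, 21, 10),
    "ion_torrent_314" = c(15, 6, 3),
    "ion_torrent_316" = c(147, 59, 29),
    "ion_torrent_318" = c(1471, 588, 294),
    "illumina_miseq" = c(2206, 882, 441),
    "illumina_hiseq2000" = c(882353, 352941, 176471),
    "illumina_hiseq2000_lane" = c(58824, 23529, 11765))
  tab <- capacityTable()
  for (p in names(expected)) {
    row <- tab[tab$platform == p, ]
    expect_equal(unname(unlist(row[, c("genomes_20x", "genomes_50x",
                                       "genomes_100x")])),
                 expected[[p]], info = p)
  }
  # cost per genome at each platform's reference coverage
  expect_equal(tab$cost_per_genome,
               c(21.37, 38.25, 7.23, 1.06, 0.85, 0.24, 0.24))
})

test_that("runCapacity is monotone and validates inputs", {
  base <- runCapacity(35e6, 20, 1100)
  expect_equal(runCapacity(35e6, 40, 1100)$raw, base$raw / 2)
  expect_gt(runCapacity(70e6, 20)$genomesPerRun, base$genomesPerRun)
  expect_lt(runCapacity(35e6, 20, genomeLength = 34000)$genomesPerRun,
            base$genomesPerRun)
  expect_gt(runCapacity(35e6, 20, mitoFraction = 0.9)$genomesPerRun,
            base$genomesPerRun)
  expect_error(runCapacity(0, 20), "positive")
  expect_error(runCapacity(35e6, -1), "positive")
})
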