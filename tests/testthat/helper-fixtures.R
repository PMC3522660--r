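# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# small random genome with a COI annotation at a known offset
testGenome <- function(id = "G1", len = 3000L, coiStart = 100L,
                       coiLen = 1545L, seed = 1L, strand = "+") {
  s <- withr::with_seed(seed, paste(sample(c("A", "C", "G", "T"), len,
                                           replace = TRUE), collapse = ""))
  genes <- data.frame(name = "COI", start = coiStart,
                      end = coiStart + coiLen, strand = strand)
  annotatedMitogenome(id, s, circular = TRUE, genes = genes)
}

# a cached 5-taxon family for the mid-weight tests
smallFamily <- function() {
  fixture("fam5", function()
    makeFamily(familySpec(5, 0.12, indelRate = 1e-4, seed = 42)))
}

# brute-force p-distance oracle on two gapped rows
oraclePDistance <- function(rowA, rowB) {
  a <- strsplit(rowA, "")[[1]]
  b <- strsplit(rowB, "")[[1]]
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  if (!sum(ok)) return(list(p = NA_real_, comparable = 0L))
  list(p = sum(a[ok] != b[ok]) / sum(ok), comparable = sum(ok))
}

# random gapped alignment pair generator
randomGappedPair <- function(len = 80, pGap = 0.1, pMut = 0.2, pN = 0.02) {
  bases <- c("A", "C", "G", "T")
  a <- sample(bases, len, replace = TRUE)
  b <- a
  mut <- runif(len) < pMut
  b[mut] <- vapply(b[mut], function(x) sample(setdiff(bases, x), 1), "")
  a[runif(len) < pGap] <- "-"
  b[runif(len) < pGap] <- "-"
  a[runif(len) < pN] <- "N"
  b[runif(len) < pN] <- "N"
  list(rowA = paste(a, collapse = ""), rowB = paste(b, collapse = ""))
}

pairAln <- function(rowA, rowB, idA = "A", idB = "B") {
  new("PairAlignment", idA = idA, idB = idB, rowA = rowA, rowB = rowB,
      method = "external", params = list())
}

# random symmetric compatibility instance as a CompatibilityMatrix
randomCompat <- function(n, pEdge, seed) {
  withr::with_seed(seed, {
    m <- matrix(FALSE, n, n)
    m[upper.tri(m)] <- runif(n * (n - 1) / 2) < pEdge
    m <- m | t(m)
  })
  ids <- sprintf("s%02d", seq_len(n))
  compatibilityFromEvidence(ids, coiProxy = ifelse(m, 0.30, 0.01),
                            policy = compatPolicy(mode = "proxy_only"))
}

# exhaustive maximum-clique size oracle (bitmask enumeration)
oracleCliqueNum <- function(adj) {
  n <- nrow(adj)
  best <- 0L
  for (mask in seq_len(2^n) - 1L) {
    v <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(v) <= best) next
    sub <- adj[v, v, drop = FALSE]
    if (all(sub[upper.tri(sub)])) best <- length(v)
  }
  best
}

# exact chromatic number oracle by backtracking
oracleChromatic <- function(adj) {
  n <- nrow(adj)
  for (k in seq_len(n)) {
    colr <- integer(n)
    rec <- function(v) {
      if (v > n) return(TRUE)
      for (cc in seq_len(k)) {
        prev <- seq_len(v - 1)
        if (!any(adj[v, prev] & colr[prev] == cc)) {
          colr[v] <<- cc
          if (rec(v + 1)) return(TRUE)
          colr[v] <<- 0L
        }
      }
      FALSE
    }
    if (rec(1)) return(k)
  }
  n
}

revcompChr <- function(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
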