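# p-distances, the Folmer proxy, anchored alignment and sliding windows.

test_that("pDistance matches hand-worked examples", {
  expect_equal(pDistance(pairAln("ACGTACGTAC", "ACGTACGTAT")),
               list(p = 0.1, comparable = 10L, status = "ok"))
  expect_equal(pDistance(pairAln("AC-GT", "ACAGT"))$p, 0)
  expect_equal(pDistance(pairAln("AC-GT", "ACAGT"))$comparable, 4L)
  same <- pDistance(pairAln("ACGTACGT", "ACGTACGT"))
  expect_equal(same$p, 0)
  allGap <- pDistance(pairAln("----", "ACGT"))
  expect_true(is.na(allGap$p))
  expect_equal(allGap$status, "no comparable sites")
})

test_that("pDistance equals the brute-force column oracle on random pairs", {
  withr::with_seed(11, {
    for (i in 1:200) {
      pr <- randomGappedPair()
      got <- pDistance(pairAln(pr$rowA, pr$rowB))
      want <- oraclePDistance(pr$rowA, pr$rowB)
      expect_equal(got$p, want$p)
      expect_equal(got$comparable, want$comparable)
    }
  })
})

test_that("pDistance is symmetric and bounded", {
  withr::with_seed(12, {
    for (i in 1:50) {
      pr <- randomGappedPair()
      p1 <- pDistance(pairAln(pr$rowA, pr$rowB))$p
      p2 <- pDistance(pairAln(pr$rowB, pr$rowA))$p
      expect_identical(p1, p2)
      if (!is.na(p1)) expect_true(p1 >= 0 && p1 <= 1)
    }
  })
})

test_that("the Folmer fragment is 651 bp for full-length COI", {
  g <- testGenome(len = 3000, coiStart = 200, coiLen = 1545)
  expect_equal(nchar(folmerFragment(g)), 651L)
  expect_equal(folmerProxy(g, g), 0)
  short <- testGenome("short", len = 2000, coiStart = 0, coiLen = 500)
  expect_warning(frag <- folmerFragment(short), "available overlap")
  expect_equal(nchar(frag), 451L)
})

test_that("a constructed pair with 98 substituted Folmer sites gives p = 98/651", {
  g <- testGenome("folmer", len = 3000, coiStart = 120, coiLen = 1545,
                  seed = 9)
  s <- as.character(genomeSeq(g))
  chars <- strsplit(s, "")[[1]]
  # Folmer window occupies COI positions 50..700 (1-based)
  sites <- withr::with_seed(10, sample(120 + 49 + 0:650, 98))
  for (p in sites + 1)
    chars[p] <- setdiff(c("A", "C", "G", "T"), chars[p])[1]
  g2 <- annotatedMitogenome("folmer2", paste(chars, collapse = ""),
                            genes = genes(g))
  expect_equal(folmerProxy(g, g2), 98 / 651, tolerance = 1e-10)
})

test_that("anchored alignment reproduces known structures", {
  fam <- smallFamily()
  a <- as.character(genomeSeq(fam$genomes[[1]]))
  b <- as.character(genomeSeq(fam$genomes[[2]]))
  aln <- alignAnchored(a, b)
  # removing gaps recovers the inputs
  expect_identical(gsub("-", "", aln@rowA), a)
  expect_identical(gsub("-", "", aln@rowB), b)
  # identical sequences align gap-free with p = 0
  self <- alignAnchored(a, a)
  expect_false(grepl("-", self@rowA, fixed = TRUE))
  expect_equal(pDistance(self)$p, 0)
  # a single deleted 10 bp block yields exactly one 10-column gap run
  withr::with_seed(5, {
    s <- paste(sample(c("A", "C", "G", "T"), 3000, TRUE), collapse = "")
  })
  s2 <- paste0(substr(s, 1, 1500), substr(s, 1511, 3000))
  gapAln <- alignAnchored(s, s2)
  runs <- rle(strsplit(gapAln@rowB, "")[[1]] == "-")
  expect_equal(sum(runs$values), 1)
  expect_equal(runs$lengths[runs$values], 10)
  # unrelated sequences are refused
  withr::with_seed(6, {
    u <- paste(sample(c("A", "C", "G", "T"), 2000, TRUE), collapse = "")
  })
  expect_error(alignAnchored(s, u), "too divergent")
})

test_that("anchored alignment is score-optimal against full NW on 2 kb pairs", {
  fam <- smallFamily()
  mat <- Biostrings::nucleotideSubstitutionMatrix(1, -1, baseOnly = TRUE)
  for (pair in list(c(1, 2), c(2, 3), c(4, 5))) {
    a <- substr(as.character(genomeSeq(fam$genomes[[pair[1]]])), 1, 2000)
    b <- substr(as.character(genomeSeq(fam$genomes[[pair[2]]])), 1, 2000)
    got <- alignmentScore(alignAnchored(a, b))
    want <- Biostrings::score(Biostrings::pairwiseAlignment(
      Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
      substitutionMatrix = mat, gapOpening = 4, gapExtension = 1))
    expect_equal(got, want)
  }
})

test_that("sliding windows: count formula, identity and artifact flagging", {
  withr::with_seed(21, {
    s <- paste(sample(c("A", "C", "G", "T"), 600, TRUE), collapse = "")
  })
  aln <- pairAln(s, s)
  prof <- slidingProfile(aln, 150, 15)
  # enumeration oracle: starts 0, 15, ... while start + 150 <= 600
  expect_equal(length(prof@p), length(seq(0, 600 - 150, by = 15)))
  expect_equal(length(prof@p), 31L)
  expect_true(all(prof@p == 0))
  expect_false(any(prof@lowInfo))
  # windows across a one-sided deletion are flagged, not reported as p = 0
  chars <- strsplit(s, "")[[1]]
  chars[101:400] <- "-"
  gapped <- pairAln(s, paste(chars, collapse = ""))
  prof2 <- slidingProfile(gapped, 150, 15)
  inside <- prof2@windowStarts >= 100 & prof2@windowStarts + 150 <= 400
  expect_true(all(prof2@lowInfo[inside]))
  expect_true(all(is.na(prof2@p[inside])))
  expect_error(slidingProfile(aln, 601, 15), "exceeds")
})

test_that("window counts follow floor((L - w)/s) + 1 across random cases", {
  withr::with_seed(22, {
    for (i in 1:20) {
      L <- sample(200:2000, 1)
      w <- sample(c(150, 450), 1)
      if (w > L) next
      st <- sample(c(15, 45), 1)
      s <- paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = "")
      prof <- slidingProfile(pairAln(s, s), w, st)
      expect_equal(length(prof@p), (L - w) %/% st + 1)
    }
  })
})

test_that("minWindowDivergence skips flagged windows", {
  prof <- new("DivergenceProfile", windowLength = 450L, step = 45L,
              windowStarts = c(0L, 45L, 90L), p = c(0.08, 0.03, 0.12),
              comparable = c(450L, 450L, 450L), lowInfo = rep(FALSE, 3),
              ids = c("a", "b"))
  expect_equal(minWindowDivergence(prof), 0.03)
  prof@p <- c(NA, 0.06, 0.07)
  prof@lowInfo <- c(TRUE, FALSE, FALSE)
  expect_equal(minWindowDivergence(prof), 0.06)
  prof@p <- rep(NA_real_, 3)
  prof@lowInfo <- rep(TRUE, 3)
  expect_true(is.na(minWindowDivergence(prof)))
})

test_that("tiled windows bracket the whole-alignment p-distance", {
  fam <- smallFamily()
  aln <- alignAnchored(fam$genomes[[1]], fam$genomes[[3]])
  prof <- slidingProfile(aln, 450, 450)   # non-overlapping tiling
  ok <- !prof@lowInfo
  whole <- pDistance(aln)$p
  expect_true(min(prof@p[ok]) <= whole + 1e-9)
  expect_true(max(prof@p[ok]) >= whole - 1e-9)
})

test_that("150 bp windows vary more than 450 bp windows on synthetic pairs", {
  fam <- smallFamily()
  n <- length(fam$genomes)
  wins <- sapply(utils::combn(n, 2, simplify = FALSE), function(pr) {
    aln <- alignAnchored(fam$genomes[[pr[1]]], fam$genomes[[pr[2]]])
    c(var(slidingProfile(aln, 150, 15)@p, na.rm = TRUE),
      var(slidingProfile(aln, 450, 45)@p, na.rm = TRUE))
  })
  expect_true(all(wins[1, ] > wins[2, ]))
})
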