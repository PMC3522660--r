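# Read simulation: haplotype mutation, pooled reads, exact tiling.

test_that("mutation rate 0 returns the genome unchanged with an empty log", {
  g <- testGenome(len = 2000, coiStart = 0, coiLen = 1545)
  res <- mutateHaplotype(g, errorModel(mutationRate = 0), seed = 1)
  expect_identical(as.character(genomeSeq(res$genome)),
                   as.character(genomeSeq(g)))
  expect_equal(nrow(res$log), 0)
})

test_that("haplotype mutation count matches the binomial expectation", {
  g <- fixture("mut17k", function() testGenome("m", len = 17000,
                                               coiStart = 0, coiLen = 1545))
  model <- errorModel(mutationRate = 0.001)
  counts <- vapply(1:200, function(sd)
    nrow(mutateHaplotype(g, model, seed = sd)$log), numeric(1))
  expect_equal(mean(counts), 17, tolerance = 0.1)
  # determinism under seed
  l1 <- mutateHaplotype(g, model, seed = 5)$log
  l2 <- mutateHaplotype(g, model, seed = 5)$log
  expect_identical(l1, l2)
})

test_that("indel lengths are geometric with mean 1/(1 - 0.3)", {
  g <- fixture("mut17k", function() testGenome("m", len = 17000,
                                               coiStart = 0, coiLen = 1545))
  model <- errorModel(mutationRate = 0.01, indelFrac = 1)
  lens <- unlist(lapply(1:60, function(sd)
    mutateHaplotype(g, model, seed = sd)$log$len))
  expect_gt(length(lens), 5000)
  expect_equal(mean(lens), 1 / 0.7, tolerance = 0.03)
})

test_that("read counts follow ceil(coverage * length / readLength)", {
  g <- testGenome("c", len = 17000, coiStart = 0, coiLen = 1545)
  rs <- simulatePool(list(g), coverage = 20, readLength = 400,
                     model = errorModel(errorRate = 0, mutationRate = 0,
                                        randomReadProb = 0), seed = 1)
  expect_equal(length(rs), 850L)
  expect_true(all(truth(rs)$origin == "c"))
})

test_that("the coverage ladder assigns 10x + 2x steps", {
  expect_equal(coverageLadder(30), seq(10, 68, by = 2))
  expect_equal(coverageLadder(30)[30], 68)
  expect_error(coverageLadder(0), "n >= 1")
})

test_that("simulated reads are exact substrings of the doubled haplotype after error correction", {
  g <- testGenome("w", len = 3000, coiStart = 0, coiLen = 1545, seed = 3)
  rs <- simulatePool(list(g), coverage = 3, readLength = 150,
                     model = errorModel(errorRate = 0, mutationRate = 0.001,
                                        randomReadProb = 0), seed = 9)
  hap <- rs@haplotypes[["w"]]
  doubled <- paste0(hap, hap)
  tr <- truth(rs)
  for (i in seq_len(length(rs))) {
    rd <- as.character(simReads(rs)[[i]])
    if (tr$strand[i] == "-") rd <- revcompChr(rd)
    expect_identical(rd, substr(doubled, tr$start[i] + 1, tr$start[i] + 150))
  }
  expect_true(any(tr$wrapped))
  expect_true(all((tr$start + 150 > 3000) == tr$wrapped))
})

test_that("per-base read errors are calibrated and recorded in the truth", {
  g <- testGenome("e", len = 15000, coiStart = 0, coiLen = 1545, seed = 4)
  rs <- simulatePool(list(g), coverage = 10, readLength = 150,
                     model = errorModel(errorRate = 0.02, mutationRate = 0,
                                        randomReadProb = 0), seed = 2)
  tr <- truth(rs)
  doubled <- paste0(as.character(genomeSeq(g)), as.character(genomeSeq(g)))
  mm <- 0L
  for (i in seq_len(length(rs))) {
    rd <- as.character(simReads(rs)[[i]])
    if (tr$strand[i] == "-") rd <- revcompChr(rd)
    ref <- substr(doubled, tr$start[i] + 1, tr$start[i] + 150)
    d <- sum(charToRaw(rd) != charToRaw(ref))
    expect_equal(d, tr$n_subs[i])
    mm <- mm + d
  }
  measured <- mm / (length(rs) * 150)
  expect_equal(measured, 0.02, tolerance = 0.1)
})

test_that("contaminant reads appear at the configured rate and coverage is additive", {
  g <- testGenome("r", len = 15000, coiStart = 0, coiLen = 1545, seed = 5)
  rs <- simulatePool(list(g), coverage = 40, readLength = 150,
                     model = errorModel(mutationRate = 0), seed = 4)
  tr <- truth(rs)
  nGenome <- sum(tr$origin == "r")
  # genome-derived reads are exactly the nominal count
  expect_equal(nGenome, ceiling(40 * 15000 / 150))
  frac <- mean(tr$origin == "RANDOM")
  expect_equal(frac, 0.05, tolerance = 0.35)
  expect_true(all(is.na(tr$start[tr$origin == "RANDOM"])))
})

test_that("simulation is byte-deterministic under a seed", {
  fam <- smallFamily()
  g <- fam$genomes[1:2]
  r1 <- simulatePool(g, c(5, 7), 150, model = errorModel(), seed = 33)
  r2 <- simulatePool(g, c(5, 7), 150, model = errorModel(), seed = 33)
  expect_identical(as.character(simReads(r1)), as.character(simReads(r2)))
  expect_identical(truth(r1), truth(r2))
  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  writeFastq(r1, f1); writeFastq(r2, f2)
  expect_identical(readLines(f1), readLines(f2))
  r3 <- simulatePool(g, c(5, 7), 150, model = errorModel(), seed = 34)
  expect_false(identical(as.character(simReads(r1)),
                         as.character(simReads(r3))))
})

test_that("paired-end mode keeps mates adjacent with sane inserts", {
  g <- testGenome("p", len = 4000, coiStart = 0, coiLen = 1545, seed = 6)
  rs <- simulatePool(list(g), coverage = 4, readLength = 150, paired = TRUE,
                     model = errorModel(errorRate = 0, mutationRate = 0,
                                        randomReadProb = 0), seed = 8)
  expect_true(all(rs@mate %in% 1:2))
  m <- rs@mate
  expect_true(all(m[seq(1, length(m), by = 2)] == 1L))
  expect_true(all(m[seq(2, length(m), by = 2)] == 2L))
  # mates share a fragment id and opposite strands
  tr <- truth(rs)
  ids <- sub("/[12]$", "", tr$read_id)
  expect_identical(ids[seq(1, length(m), 2)], ids[seq(2, length(m), 2)])
  expect_true(all(tr$strand[seq(1, length(m), 2)] !=
                  tr$strand[seq(2, length(m), 2)]))
  expect_error(simulatePool(list(g), 4, 150, paired = TRUE,
                            insertMean = 100, model = errorModel(), seed = 1),
               "insert")
})

test_that("exact reads tile the circle uniformly, including the origin", {
  g <- testGenome("t", len = 1000, coiStart = 0, coiLen = 600, seed = 7)
  rs <- exactReads(g, readLength = 100, step = 50)
  expect_equal(length(rs), 20L)
  # per-base coverage is exactly readLength / step
  cov <- integer(1000)
  tr <- truth(rs)
  for (i in seq_len(nrow(tr))) {
    pos <- (tr$start[i] + 0:99) %% 1000
    cov[pos + 1] <- cov[pos + 1] + 1L
  }
  expect_true(all(cov == 2L))
  # wrapping read covers the tail and the head
  wrap <- as.character(simReads(rs)[[20]])
  s <- as.character(genomeSeq(g))
  expect_identical(wrap, paste0(substr(s, 951, 1000), substr(s, 1, 50)))
  # step = readLength gives a 1x non-overlapping tiling
  rs1 <- exactReads(g, 100, 100)
  expect_equal(length(rs1), 10L)
})

test_that("FASTQ output carries the quality implied by the error rate", {
  g <- testGenome("q", len = 600, coiStart = 0, coiLen = 500, seed = 8)
  rs <- simulatePool(list(g), 2, 100,
                     model = errorModel(errorRate = 0.02, mutationRate = 0,
                                        randomReadProb = 0), seed = 1)
  path <- withr::local_tempfile(fileext = ".fastq")
  writeFastq(rs, path)
  lines <- readLines(path)
  expect_equal(length(lines) %% 4, 0)
  quals <- lines[seq(4, length(lines), by = 4)]
  # Q17 = round(-10 log10 0.02) -> '2' in Phred+33
  expect_true(all(unlist(strsplit(quals, "")) == rawToChar(as.raw(17 + 33))))
})
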