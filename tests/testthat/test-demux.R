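# Demultiplexing: reference assignment, truth mapping, overlap summaries.

test_that("a contig equal to a reference marker is assigned with score 1", {
  fam <- smallFamily()
  refdb <- referenceFromGenomes(fam$genomes)
  coi1 <- sliceCircular(fam$genomes[[1]], 0, 1545)
  asn <- assignContigs(Biostrings::DNAStringSet(c(q = coi1)), refdb)
  expect_equal(asn$status, "assigned")
  expect_equal(asn$best_taxon, "T01")
  expect_equal(asn$best_score, 1)
  expect_equal(asn$markers_hit, "COI")
  # reverse complement gives the same assignment (canonical k-mers)
  asnRc <- assignContigs(Biostrings::DNAStringSet(c(q = revcompChr(coi1))),
                         refdb)
  expect_equal(asnRc$best_taxon, "T01")
  expect_equal(asnRc$best_score, 1)
})

test_that("random contigs stay unassigned and empty databases error", {
  fam <- smallFamily()
  refdb <- referenceFromGenomes(fam$genomes)
  withr::with_seed(41, {
    rnd <- paste(sample(c("A", "C", "G", "T"), 1000, TRUE), collapse = "")
  })
  asn <- assignContigs(Biostrings::DNAStringSet(c(r = rnd)), refdb)
  expect_equal(asn$status, "unassigned")
  expect_lt(asn$best_score, 0.2)
  expect_error(assignContigs(Biostrings::DNAStringSet(c(r = rnd)),
                             new("ReferenceDB", taxa = character(0),
                                 markers = character(0),
                                 seqs = Biostrings::DNAStringSet(),
                                 k = 15L, index = list())),
               "empty")
})

test_that("reference FASTA with taxon|marker headers round-trips", {
  fam <- smallFamily()
  path <- withr::local_tempfile(fileext = ".fasta")
  seqs <- Biostrings::DNAStringSet(vapply(fam$genomes, function(g)
    sliceCircular(g, 0, 1545), character(1)))
  names(seqs) <- paste0(vapply(fam$genomes, genomeId, ""), "|COI")
  Biostrings::writeXStringSet(seqs, path)
  db <- readReferenceFasta(path)
  expect_identical(db@taxa, vapply(fam$genomes, genomeId, ""))
  expect_true(all(db@markers == "COI"))
})

test_that("exact substrings map back with identity 1, including across the origin", {
  fam <- smallFamily()
  g <- fam$genomes[[1]]
  L <- length(g)
  spanning <- sliceCircular(g, L - 500, L - 500 + 1200)   # wraps the origin
  pl <- mapContigsToTruth(Biostrings::DNAStringSet(c(w = spanning)),
                          fam$genomes)
  expect_equal(pl$genome, "T01")
  expect_equal(pl$identity, 1)
  expect_true(pl$wrapped)
  expect_equal(pl$start, L - 500)
  expect_false(pl$chimeric)
  # reverse-complemented contig: minus strand, same placement
  plRc <- mapContigsToTruth(Biostrings::DNAStringSet(c(w = revcompChr(spanning))),
                            fam$genomes)
  expect_equal(plRc$genome, "T01")
  expect_equal(plRc$strand, "-")
  expect_equal(plRc$identity, 1)
})

test_that("a concatenation of two genomes' fragments is flagged chimeric", {
  fam <- smallFamily()
  chim <- paste0(sliceCircular(fam$genomes[[1]], 0, 1000),
                 sliceCircular(fam$genomes[[2]], 3000, 4000))
  pl <- mapContigsToTruth(Biostrings::DNAStringSet(c(chi = chim)),
                          fam$genomes)
  expect_true(pl$chimeric)
})

test_that("contigs from a mutated haplotype keep high identity on their genome", {
  fam <- smallFamily()
  g <- fam$genomes[[1]]
  mut <- mutateHaplotype(g, errorModel(mutationRate = 0.001), seed = 77)
  frag <- substr(as.character(genomeSeq(mut$genome)), 2001, 5000)
  pl <- mapContigsToTruth(Biostrings::DNAStringSet(c(m = frag)), fam$genomes)
  expect_equal(pl$genome, "T01")
  expect_gte(pl$identity, 0.99)
})

test_that("overlap fractions use the configured denominator and strict thresholds", {
  g <- testGenome("g1", len = 16000, coiStart = 0, coiLen = 1545, seed = 51)
  pl <- data.frame(contig_id = "c1", genome = "g1", start = 100L,
                   end = 100L + 8400L, strand = "+", identity = 1,
                   wrapped = FALSE, chimeric = FALSE, n_anchors = 100L)
  ov <- overlapSummary(pl, list(g), denominatorMode = "fixed_16400")
  expect_equal(ov$perGenome$best_fraction, 8400 / 16400, tolerance = 1e-12)
  expect_equal(unname(ov$poolCounts["gt50"]), 1L)   # 0.512 > 0.5, strict
  expect_equal(unname(ov$poolCounts["gt67"]), 0L)
  ovOwn <- overlapSummary(pl, list(g))
  expect_equal(ovOwn$perGenome$best_fraction, 8400 / 16000)
  # exactly-at-threshold does not count (strict >)
  plHalf <- transform(pl, end = start + 8000L)
  ovHalf <- overlapSummary(plHalf, list(g))
  expect_equal(unname(ovHalf$poolCounts["gt50"]), 0L)
  # no contigs -> fraction 0; full circle -> fraction 1
  ovNone <- overlapSummary(pl[0, ], list(g))
  expect_equal(ovNone$perGenome$best_fraction, 0)
  plFull <- transform(pl, start = 0L, end = 16000L)
  expect_equal(overlapSummary(plFull, list(g))$perGenome$best_fraction, 1)
  expect_error(overlapSummary(pl, list(g), thresholds = c(0, 0.5)), "thresholds")
})

test_that("overlap summary is invariant to contig order and genome rotation", {
  fam <- smallFamily()
  g <- fam$genomes[1:2]
  pool <- poolReadSets(lapply(g, exactReads, readLength = 200, step = 10))
  ctg <- assembleReads(pool, k = 31, minCount = 1)
  pl <- mapContigsToTruth(ctg, g)
  ov1 <- overlapSummary(pl, g)
  ov2 <- overlapSummary(pl[rev(seq_len(nrow(pl))), ], g)
  expect_equal(ov1$poolCounts, ov2$poolCounts)
  expect_equal(ov1$perGenome$best_fraction, ov2$perGenome$best_fraction)
  # rotate the truth genomes: fractions against own length are unchanged
  rot <- lapply(g, function(x) {
    s <- as.character(genomeSeq(x))
    annotatedMitogenome(genomeId(x), paste0(substr(s, 1001, nchar(s)),
                                            substr(s, 1, 1000)),
                        genes = emptyGeneTable())
  })
  pl2 <- mapContigsToTruth(ctg, rot)
  ov3 <- overlapSummary(pl2, rot)
  expect_equal(ov3$perGenome$best_fraction, ov1$perGenome$best_fraction,
               tolerance = 1e-6)
})

test_that("circular union of placements caps at the genome length", {
  g <- testGenome("u", len = 1000, coiStart = 0, coiLen = 600, seed = 52)
  pl <- data.frame(contig_id = c("a", "b"), genome = "u",
                   start = c(800L, 100L), end = c(1200L, 500L), strand = "+",
                   identity = 1, wrapped = c(TRUE, FALSE), chimeric = FALSE,
                   n_anchors = 10L)
  ov <- overlapSummary(pl, list(g))
  # [800,1200) wraps to [800,1000)+[0,200); with [100,500) the circular
  # union covers [800,1000) and [0,500): 200 + 500 = 700 bases
  expect_equal(ov$perGenome$covered_bp, 700L)
})

test_that("tetranucleotide profiles are normalised sliding counts", {
  p <- tetraProfile("AAAA")
  expect_equal(unname(p["AAAA"]), 1)
  expect_equal(sum(p), 1)
  p2 <- tetraProfile("ACGTACGT")
  expect_equal(unname(p2["ACGT"]), 0.4)
  expect_equal(unname(p2[c("CGTA", "GTAC", "TACG")]), rep(0.2, 3))
  expect_equal(sum(p2), 1)
  expect_length(p2, 256)
  expect_error(tetraProfile("ACG"), "at least 4")
  withr::with_seed(53, {
    s <- paste(sample(c("A", "C", "G", "T"), 500, TRUE), collapse = "")
  })
  expect_equal(sum(tetraProfile(s)), 1)
})
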