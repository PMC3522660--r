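## Read simulation from pooled circular mitogenomes with truth tracking.

#' Error model for read simulation
#'
#' Two-level parameterisation: each genome first receives haplotype
#' mutations once per run (rate `mutationRate` per site, of which
#' `indelFrac` are indels whose length is geometric with extension
#' probability `indelExt`), then each read receives independent
#' per-base substitution errors at `errorRate`. With probability
#' `randomReadProb` a read in the pool is uniform random DNA
#' (library contamination).
#'
#' @param errorRate per-base substitution probability in reads (default 0.02).
#' @param mutationRate per-base haplotype mutation probability (default 0.001).
#' @param indelFrac fraction of haplotype mutations that are indels
#'   (default 0.1).
#' @param indelExt probability an indel extends by one base (default 0.3;
#'   length is 1 + Geometric(1 - indelExt)).
#' @param randomReadProb probability a pooled read is random DNA
#'   (default 0.05).
#' @param homopolymerMode experimental: re-weight read errors towards
#'   indels inside homopolymers of length >= 3 (off by default).
#' @return a validated list of class `ErrorModel`.
#' @export
errorModel <- function(errorRate = 0.02, mutationRate = 0.001,
                       indelFrac = 0.1, indelExt = 0.3,
                       randomReadProb = 0.05, homopolymerMode = FALSE) {
  p <- c(errorRate, mutationRate, indelFrac, indelExt, randomReadProb)
  if (any(p < 0 | p > 1)) stop("all model probabilities must lie in [0,1]")
  structure(list(errorRate = errorRate, mutationRate = mutationRate,
                 indelFrac = indelFrac, indelExt = indelExt,
                 randomReadProb = randomReadProb,
                 homopolymerMode = isTRUE(homopolymerMode)),
            class = "ErrorModel")
}

#' Coverage ladder
#'
#' Genome i of n receives coverage `start + step * (i - 1)`; the
#' conventional ladder runs from 10x in steps of 2x (so the 30th genome
#' sits at 68x), emulating non-equimolar pooling.
#'
#' @param n number of genomes.
#' @param start coverage of the first genome (default 10).
#' @param step increment (default 2).
#' @return numeric vector of length `n`.
#' @export
coverageLadder <- function(n, start = 10, step = 2) {
  if (n < 1 || start <= 0) stop("need n >= 1 and positive start coverage")
  start + step * (seq_len(n) - 1)
}

.BASES <- c("A", "C", "G", "T")

.randomDna <- function(n) paste(sample(.BASES, n, replace = TRUE), collapse = "")

#' Apply haplotype mutations to a genome
#'
#' Each site mutates independently with probability `mutationRate`; a
#' mutation is an indel with probability `indelFrac` (length
#' 1 + Geometric(1 - indelExt), capped at 10, insertion or deletion with
#' equal probability) and otherwise a substitution to one of the three
#' alternative bases. Gene annotations are re-mapped through the indel
#' offsets. Deterministic under `seed`.
#'
#' @param genome an [AnnotatedMitogenome-class].
#' @param model an [errorModel()].
#' @param seed integer seed.
#' @return list with `genome` (mutated copy) and `log` (data.frame of
#'   events: `pos` 0-based on the input genome, `type`, `ref`, `alt`,
#'   `len`).
#' @export
mutateHaplotype <- function(genome, model, seed = 1L) {
  s <- as.character(genome@seq)
  L <- nchar(s)
  emptyLog <- data.frame(pos = integer(), type = character(),
                         ref = character(), alt = character(),
                         len = integer(), stringsAsFactors = FALSE)
  hit <- integer(0)
  if (model$mutationRate > 0)
    withr::with_seed(as.integer(seed),
                     hit <- which(runif(L) < model$mutationRate))
  if (!length(hit)) return(list(genome = genome, log = emptyLog))
  withr::with_seed(as.integer(seed) + 1L, {
    isIndel <- runif(length(hit)) < model$indelFrac
    chars <- strsplit(s, "")[[1]]
    log <- vector("list", length(hit))
    ## substitutions first (no coordinate shifts)
    for (i in which(!isIndel)) {
      p <- hit[i]
      ref <- chars[p]
      alt <- sample(setdiff(.BASES, ref), 1)
      chars[p] <- alt
      log[[i]] <- data.frame(pos = p - 1L, type = "sub", ref = ref,
                             alt = alt, len = 1L)
    }
    ## indels applied right-to-left so earlier positions stay valid
    idx <- which(isIndel)
    lens <- pmin(1L + stats::rgeom(length(idx), 1 - model$indelExt), 10L)
    ins <- runif(length(idx)) < 0.5
    ord <- order(hit[idx], decreasing = TRUE)
    for (r in seq_along(ord)) {
      i <- idx[ord[r]]
      p <- hit[i]
      len <- lens[ord[r]]
      if (ins[ord[r]]) {
        insSeq <- paste(sample(.BASES, len, replace = TRUE), collapse = "")
        chars <- append(chars, strsplit(insSeq, "")[[1]], after = p)
        log[[i]] <- data.frame(pos = p - 1L, type = "ins", ref = "",
                               alt = insSeq, len = len)
      } else {
        delTo <- min(p + len - 1L, length(chars))
        ref <- paste(chars[p:delTo], collapse = "")
        chars <- chars[-(p:delTo)]
        log[[i]] <- data.frame(pos = p - 1L, type = "del", ref = ref,
                               alt = "", len = delTo - p + 1L)
      }
    }
    log <- do.call(rbind, log)
    log <- log[order(log$pos), ]
    rownames(log) <- NULL
    newSeq <- paste(chars, collapse = "")
    ## re-map annotations through cumulative indel offsets
    g <- genome@genes
    if (nrow(g)) {
      indels <- log[log$type != "sub", , drop = FALSE]
      shift <- function(x) {
        if (!nrow(indels)) return(x)
        delta <- ifelse(indels$type == "ins", indels$len, -indels$len)
        vapply(x, function(b) b + sum(delta[indels$pos < b]), numeric(1))
      }
      g$start <- pmax(0L, as.integer(shift(g$start)))
      g$end <- pmax(g$start + 1L, as.integer(shift(g$end)))
      g$end <- pmin(g$end, nchar(newSeq) + pmax(0L, g$end - nchar(newSeq)))
    }
    mut <- annotatedMitogenome(genome@id, newSeq, circular = genome@circular,
                               genes = g, source = genome@source)
    list(genome = mut, log = log)
  })
}

## vectorised substitution errors on a character vector of reads;
## returns list(reads, nSubs)
.addReadErrors <- function(reads, errorRate) {
  nSubs <- integer(length(reads))
  if (errorRate <= 0 || !length(reads)) return(list(reads = reads, nSubs = nSubs))
  widths <- nchar(reads)
  nErr <- rbinom(length(reads), widths, errorRate)
  for (i in which(nErr > 0L)) {
    pos <- sample.int(widths[i], nErr[i])
    chars <- strsplit(reads[i], "")[[1]]
    for (p in pos) chars[p] <- sample(setdiff(.BASES, chars[p]), 1)
    reads[i] <- paste(chars, collapse = "")
    nSubs[i] <- nErr[i]
  }
  list(reads = reads, nSubs = nSubs)
}

#' Simulate a pooled read set from circular mitogenomes
#'
#' Per genome, exactly `ceil(coverage * length / readLength)`
#' genome-derived reads (pairs count both mates) are drawn with start
#' positions uniform on the circle (reads may span the origin) and
#' uniform strand; a haplotype carrying the model's mutations is drawn
#' once per genome and per-base substitution errors are applied to every
#' read. Contaminant reads of uniform random DNA are added on top, one
#' expected per `1/randomReadProb - 1` genome-derived reads, so the
#' realized genome coverage stays at its nominal value while the pooled
#' RANDOM-read fraction has mean `randomReadProb`. All reads are pooled
#' and shuffled; everything is deterministic under `seed`.
#'
#' @param genomes list of [AnnotatedMitogenome-class] objects.
#' @param coverage numeric coverage per genome (recycled; see
#'   [coverageLadder()]).
#' @param readLength fixed read length in bp.
#' @param paired simulate paired ends (insert `insertMean` +/- `insertSd`,
#'   truncated at `readLength`).
#' @param model an [errorModel()].
#' @param seed integer seed.
#' @param insertMean,insertSd paired-end insert size parameters
#'   (default 500 +/- 50).
#' @return a [SimulatedReadSet-class].
#' @export
simulatePool <- function(genomes, coverage, readLength, paired = FALSE,
                         model = errorModel(), seed = 1L,
                         insertMean = 500, insertSd = 50) {
  if (!length(genomes)) stop("genomes must be non-empty")
  lens <- vapply(genomes, length, integer(1))
  if (readLength > min(lens)) stop("readLength exceeds the shortest genome")
  if (paired && insertMean < readLength)
    stop("paired-end insert size must be at least the read length")
  coverage <- rep_len(coverage, length(genomes))
  seed <- as.integer(seed)
  allReads <- character(0); allMate <- integer(0)
  truthList <- list()
  haps <- list()
  withr::with_seed(seed, {
    subSeeds <- sample.int(.Machine$integer.max - 1L, length(genomes))
  })
  for (gi in seq_along(genomes)) {
    g <- genomes[[gi]]
    mut <- mutateHaplotype(g, model, seed = subSeeds[gi])
    hap <- as.character(mut$genome@seq)
    haps[[g@id]] <- hap
    L <- nchar(hap)
    doubled <- paste0(hap, hap)
    nGenome <- as.integer(ceiling(coverage[gi] * L / readLength))
    withr::with_seed(subSeeds[gi] + 1L, {
      if (!paired) {
        starts <- sample.int(L, nGenome, replace = TRUE) - 1L
        strands <- sample(c("+", "-"), nGenome, replace = TRUE)
        raw <- substring(doubled, starts + 1L, starts + readLength)
        neg <- strands == "-"
        if (any(neg))
          raw[neg] <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAStringSet(raw[neg])))
        err <- .addReadErrors(raw, model$errorRate)
        mate <- rep(0L, nGenome)
        tr <- data.frame(origin = g@id, start = starts, strand = strands,
                         n_subs = err$nSubs, n_indels = 0L,
                         wrapped = starts + readLength > L)
        reads <- err$reads
      } else {
        nPairs <- as.integer(ceiling(nGenome / 2))
        ins <- pmax(readLength, round(rnorm(nPairs, insertMean, insertSd)))
        ins <- pmin(ins, L)
        fragStart <- sample.int(L, nPairs, replace = TRUE) - 1L
        fragStrand <- sample(c("+", "-"), nPairs, replace = TRUE)
        ## mate 1 at the fragment 5' end, mate 2 reverse-complemented
        ## from the fragment 3' end, on the fragment's strand
        s1 <- fragStart
        s2 <- (fragStart + ins - readLength) %% L
        r1 <- substring(doubled, s1 + 1L, s1 + readLength)
        r2raw <- substring(doubled, s2 + 1L, s2 + readLength)
        r2 <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAStringSet(r2raw)))
        neg <- fragStrand == "-"
        if (any(neg)) {
          r1[neg] <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAStringSet(r1[neg])))
          r2[neg] <- r2raw[neg]
        }
        raw <- c(rbind(r1, r2))
        err <- .addReadErrors(raw, model$errorRate)
        reads <- err$reads
        mate <- rep(c(1L, 2L), nPairs)
        starts <- c(rbind(s1, s2))
        strands <- c(rbind(fragStrand, ifelse(fragStrand == "+", "-", "+")))
        tr <- data.frame(origin = g@id, start = starts, strand = strands,
                         n_subs = err$nSubs, n_indels = 0L,
                         wrapped = starts + readLength > L)
      }
      ## additive contamination: expected fraction randomReadProb of the pool
      p <- model$randomReadProb
      nRandom <- if (p > 0) rbinom(1L, length(reads), p / (1 - p)) else 0L
      if (nRandom > 0) {
        rnd <- vapply(seq_len(nRandom), function(i) .randomDna(readLength),
                      character(1))
        reads <- c(reads, rnd)
        mate <- c(mate, rep(0L, nRandom))
        tr <- rbind(tr, data.frame(origin = rep("RANDOM", nRandom),
                                   start = NA_integer_,
                                   strand = NA_character_, n_subs = 0L,
                                   n_indels = 0L, wrapped = FALSE))
      }
    })
    allReads <- c(allReads, reads)
    allMate <- c(allMate, mate)
    truthList[[gi]] <- tr
  }
  truth <- do.call(rbind, truthList)
  if (paired) {
    ## shuffle at the fragment level so mates stay adjacent
    frag <- cumsum(allMate != 2L)
    withr::with_seed(seed + 1L, fperm <- sample(unique(frag)))
    perm <- order(match(frag, fperm))
  } else {
    withr::with_seed(seed + 1L, perm <- sample.int(length(allReads)))
  }
  allReads <- allReads[perm]
  allMate <- allMate[perm]
  truth <- truth[perm, , drop = FALSE]
  ## paired mates share one fragment number with a /1 /2 suffix
  fragIdx <- cumsum(allMate != 2L)
  ids <- sprintf("read%06d", fragIdx)
  ids[allMate > 0L] <- paste0(ids[allMate > 0L], "/", allMate[allMate > 0L])
  truth <- cbind(read_id = ids, truth)
  rownames(truth) <- NULL
  reads <- Biostrings::DNAStringSet(allReads)
  names(reads) <- ids
  obj <- new("SimulatedReadSet", reads = reads, mate = allMate,
             truth = truth, haplotypes = haps,
             params = list(coverage = coverage, readLength = readLength,
                           paired = paired, model = model, seed = seed))
  validObject(obj)
  obj
}

#' Error-free reads tiling a circular genome
#'
#' Reads start every `step` bases around the circle (including
#' origin-spanning starts), giving uniform coverage `readLength / step`
#' when `step` divides the genome length.
#'
#' @param genome an [AnnotatedMitogenome-class].
#' @param readLength read length (must not exceed the genome).
#' @param step distance between consecutive read starts.
#' @return a [SimulatedReadSet-class].
#' @export
exactReads <- function(genome, readLength, step) {
  L <- length(genome@seq)
  if (readLength > L) stop("readLength exceeds genome length")
  if (step < 1) stop("step must be positive")
  starts <- seq.int(0L, L - 1L, by = step)
  doubled <- paste0(as.character(genome@seq), as.character(genome@seq))
  reads <- substring(doubled, starts + 1L, starts + readLength)
  ids <- sprintf("%s|%d|+", genome@id, starts)
  truth <- data.frame(read_id = ids, origin = genome@id, start = starts,
                      strand = "+", n_subs = 0L, n_indels = 0L,
                      wrapped = starts + readLength > L)
  set <- Biostrings::DNAStringSet(reads)
  names(set) <- ids
  new("SimulatedReadSet", reads = set, mate = rep(0L, length(reads)),
      truth = truth, haplotypes = setNames(list(as.character(genome@seq)),
                                           genome@id),
      params = list(readLength = readLength, step = step, exact = TRUE))
}

#' Pool several read sets into one
#'
#' @param readSets list of [SimulatedReadSet-class] objects.
#' @return a combined [SimulatedReadSet-class] (reads concatenated in
#'   order; re-shuffle with [simulatePool()]'s seed machinery if needed).
#' @export
poolReadSets <- function(readSets) {
  reads <- do.call(c, lapply(readSets, function(x) x@reads))
  mate <- unlist(lapply(readSets, function(x) x@mate), use.names = FALSE)
  truth <- do.call(rbind, lapply(readSets, function(x) x@truth))
  haps <- do.call(c, lapply(readSets, function(x) x@haplotypes))
  rownames(truth) <- NULL
  new("SimulatedReadSet", reads = reads, mate = mate, truth = truth,
      haplotypes = haps, params = list(pooled = TRUE))
}

#' Write a read set as FASTQ (Sanger Phred+33)
#'
#' Simulated bases carry a constant quality of
#' `round(-10 * log10(errorRate))` (capped at 40 for error-free reads).
#'
#' @param readSet a [SimulatedReadSet-class].
#' @param path output FASTQ.
#' @export
writeFastq <- function(readSet, path) {
  e <- readSet@params$model$errorRate %||% 0
  q <- if (is.null(e) || e <= 0) 40L else min(40L, as.integer(round(-10 * log10(e))))
  quals <- Biostrings::PhredQuality(
    vapply(Biostrings::width(readSet@reads),
           function(w) paste(rep(rawToChar(as.raw(q + 33L)), w), collapse = ""),
           character(1)))
  Biostrings::writeXStringSet(readSet@reads, path, format = "fastq",
                              qualities = Biostrings::BStringSet(quals))
  invisible(path)
}

#' Write the truth table of a read set as TSV
#'
#' @param readSet a [SimulatedReadSet-class].
#' @param path output TSV.
#' @export
writeTruthTsv <- function(readSet, path) {
  write.table(readSet@truth, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
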