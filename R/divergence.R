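## Pairwise p-distances, the Folmer COI proxy and sliding-window profiles.

## byte codes for fast column comparison
.ACGT <- charToRaw("ACGT")

.alnBytes <- function(aln) {
  list(a = charToRaw(aln@rowA), b = charToRaw(aln@rowB))
}

#' Pairwise p-distance over an alignment (pairwise deletion)
#'
#' The p-distance is the fraction of mismatching columns among columns
#' where both rows carry an unambiguous base (A, C, G or T). Gap and N
#' columns are excluded ("pairwise deletion"), so locally indel-rich
#' alignments remain comparable.
#'
#' @param aln a [PairAlignment-class].
#' @param colRange optional 0-based half-open column range `c(start, end)`.
#' @return list with `p` (fraction, `NA` when no column is comparable) and
#'   `comparable` (number of scored columns).
#' @export
pDistance <- function(aln, colRange = NULL) {
  stopifnot(is(aln, "PairAlignment"))
  by <- .alnBytes(aln)
  a <- by$a; b <- by$b
  if (!is.null(colRange)) {
    if (colRange[1] < 0 || colRange[2] > length(a) || colRange[1] >= colRange[2])
      stop("colRange outside alignment")
    idx <- (colRange[1] + 1):colRange[2]
    a <- a[idx]; b <- b[idx]
  }
  comp <- (a %in% .ACGT) & (b %in% .ACGT)
  n <- sum(comp)
  if (n == 0)
    return(list(p = NA_real_, comparable = 0L, status = "no comparable sites"))
  list(p = sum(a[comp] != b[comp]) / n, comparable = as.integer(n),
       status = "ok")
}

#' Extract the Folmer barcode fragment of the COI gene
#'
#' Positions 50-700 of the COI sequence, read as 1-based inclusive, i.e.
#' the conventional ~650 bp 5' barcode region (651 bp when COI is at
#' least 700 bp long). Shorter COI annotations yield the available
#' overlap with a warning.
#'
#' @param genome an [AnnotatedMitogenome-class] with a COI annotation.
#' @return character string (the fragment, forward orientation).
#' @export
folmerFragment <- function(genome) {
  g <- genome@genes
  hit <- which(g$name == "COI")
  if (!length(hit)) stop("genome '", genome@id, "' has no COI annotation")
  hit <- hit[1]
  coiLen <- g$end[hit] - g$start[hit]
  if (coiLen < 700)
    warning("COI of '", genome@id, "' is ", coiLen,
            " bp (< 700); using available overlap")
  from <- 49L                       # 1-based position 50
  to <- min(700L, coiLen)           # 1-based position 700, inclusive
  if (to <= from) stop("COI of '", genome@id, "' too short for the Folmer fragment")
  coi <- if (g$strand[hit] == "+") {
    sliceCircular(genome, g$start[hit], g$end[hit])
  } else {
    as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(sliceCircular(genome, g$start[hit], g$end[hit]))))
  }
  substr(coi, from + 1L, to)
}

#' Folmer COI proxy divergence between two genomes
#'
#' Aligns the two Folmer fragments globally and returns their p-distance;
#' this single number is the screening proxy for whole-mitogenome
#' divergence when full sliding-window profiles are unavailable.
#'
#' @param genomeA,genomeB [AnnotatedMitogenome-class] objects with COI
#'   annotations.
#' @return p-distance of the aligned fragments (fraction in `[0,1]`).
#' @export
folmerProxy <- function(genomeA, genomeB) {
  fa <- folmerFragment(genomeA)
  fb <- folmerFragment(genomeB)
  fit <- cpp_nw(fa, fb, 1, -1, 4, 1)
  aln <- new("PairAlignment", idA = genomeA@id, idB = genomeB@id,
             rowA = fit$a, rowB = fit$b, method = "anchored",
             params = list(match = 1, mismatch = -1, gapOpen = 4, gapExt = 1))
  pDistance(aln)$p
}

## longest strictly-increasing subsequence (patience), returns indices
.lisIndices <- function(x) {
  n <- length(x)
  if (!n) return(integer())
  tailVals <- numeric(0)
  tailIdx <- integer(0)
  prev <- integer(n)
  for (i in seq_len(n)) {
    j <- findInterval(x[i] - 0.5, tailVals) + 1L
    tailVals[j] <- x[i]
    tailIdx[j] <- i
    prev[i] <- if (j > 1L) tailIdx[j - 1L] else 0L
  }
  out <- integer(length(tailVals))
  k <- tailIdx[length(tailIdx)]
  for (j in rev(seq_along(out))) {
    out[j] <- k
    k <- prev[k]
  }
  out
}

#' Anchored global pairwise alignment
#'
#' Chains unique shared k-mers (default k = 15) as exact anchors, then
#' fills the inter-anchor segments with affine-gap Needleman-Wunsch
#' (match +1, mismatch -1, gap open -4, gap extend -1). Intended for
#' closely related mitogenomes; sequence pairs without at least three
#' collinear anchors are refused so an external alignment can be supplied
#' instead.
#'
#' @param seqA,seqB ungapped sequences (character,
#'   [Biostrings::DNAString] or [AnnotatedMitogenome-class]).
#' @param idA,idB labels (taken from genomes when given).
#' @param k anchor k-mer length (default 15).
#' @param maxFill largest inter-anchor segment the NW filler accepts
#'   (default 5000 columns).
#' @return a [PairAlignment-class] with `method = "anchored"`.
#' @export
alignAnchored <- function(seqA, seqB, idA = "A", idB = "B", k = 15L,
                          maxFill = 5000L) {
  if (is(seqA, "AnnotatedMitogenome")) { idA <- seqA@id; seqA <- as.character(seqA@seq) }
  if (is(seqB, "AnnotatedMitogenome")) { idB <- seqB@id; seqB <- as.character(seqB@seq) }
  seqA <- as.character(seqA); seqB <- as.character(seqB)
  kmA <- substring(seqA, seq_len(nchar(seqA) - k + 1),
                   seq_len(nchar(seqA) - k + 1) + k - 1)
  kmB <- substring(seqB, seq_len(nchar(seqB) - k + 1),
                   seq_len(nchar(seqB) - k + 1) + k - 1)
  uA <- !(duplicated(kmA) | duplicated(kmA, fromLast = TRUE))
  uB <- !(duplicated(kmB) | duplicated(kmB, fromLast = TRUE))
  posB <- setNames(which(uB), kmB[uB])
  selA <- which(uA & kmA %in% names(posB))
  if (length(selA) < 3)
    stop("sequences too divergent for anchored alignment; supply external alignment")
  pa <- selA                       # 1-based anchor starts in A, increasing
  pb <- unname(posB[kmA[pa]])
  keepLis <- .lisIndices(pb)
  pa <- pa[keepLis]; pb <- pb[keepLis]
  ## enforce non-overlapping anchors (same-diagonal anchors may touch)
  keep <- logical(length(pa))
  lastA <- -Inf; lastB <- -Inf; lastDiag <- NA
  for (i in seq_along(pa)) {
    d <- pb[i] - pa[i]
    if ((pa[i] >= lastA + k && pb[i] >= lastB + k) ||
        (identical(d, lastDiag) && pa[i] > lastA && pb[i] > lastB)) {
      keep[i] <- TRUE
      lastA <- pa[i]; lastB <- pb[i]; lastDiag <- d
    }
  }
  pa <- pa[keep]; pb <- pb[keep]
  if (length(pa) < 3)
    stop("sequences too divergent for anchored alignment; supply external alignment")
  ## assemble: head + (anchor, fill)* + tail
  outA <- character(0); outB <- character(0)
  curA <- 1L; curB <- 1L
  fill <- function(sa, sb) {
    if (nchar(sa) > maxFill || nchar(sb) > maxFill)
      stop("inter-anchor gap exceeds maxFill (", maxFill, " columns)")
    f <- cpp_nw(sa, sb, 1, -1, 4, 1)
    list(f$a, f$b)
  }
  for (i in seq_along(pa)) {
    ## same-diagonal anchors may overlap the previously consumed run;
    ## start this anchor's exact block where the last one ended
    fromA <- max(pa[i], curA)
    fromB <- pb[i] + (fromA - pa[i])
    segA <- substr(seqA, curA, fromA - 1L)
    segB <- substr(seqB, curB, fromB - 1L)
    if (nchar(segA) || nchar(segB)) {
      f <- fill(segA, segB)
      outA <- c(outA, f[[1]]); outB <- c(outB, f[[2]])
    }
    endA <- pa[i] + k - 1L
    endB <- pb[i] + k - 1L
    outA <- c(outA, substr(seqA, fromA, endA))
    outB <- c(outB, substr(seqB, fromB, endB))
    curA <- endA + 1L; curB <- endB + 1L
  }
  segA <- substr(seqA, curA, nchar(seqA))
  segB <- substr(seqB, curB, nchar(seqB))
  if (nchar(segA) || nchar(segB)) {
    f <- fill(segA, segB)
    outA <- c(outA, f[[1]]); outB <- c(outB, f[[2]])
  }
  aln <- new("PairAlignment", idA = idA, idB = idB,
             rowA = paste(outA, collapse = ""),
             rowB = paste(outB, collapse = ""),
             method = "anchored",
             params = list(k = k, match = 1, mismatch = -1,
                           gapOpen = 4, gapExt = 1, maxFill = maxFill))
  validObject(aln)
  aln
}

#' Score a pairwise alignment under the package's NW parameters
#'
#' A gap run of length L costs `gapOpen + L * gapExt`; matches score
#' `match`, mismatches `mismatch`. Used to compare the anchored aligner
#' against score-optimal global alignments.
#'
#' @param aln a [PairAlignment-class].
#' @param match,mismatch,gapOpen,gapExt scoring parameters.
#' @return numeric alignment score.
#' @export
alignmentScore <- function(aln, match = 1, mismatch = -1, gapOpen = 4,
                           gapExt = 1) {
  a <- strsplit(aln@rowA, "")[[1]]
  b <- strsplit(aln@rowB, "")[[1]]
  gapA <- a == "-"; gapB <- b == "-"
  both <- !gapA & !gapB
  score <- sum(ifelse(a[both] == b[both], match, mismatch))
  runs <- function(g) {
    r <- rle(g)
    lens <- r$lengths[r$values]
    if (!length(lens)) 0 else sum(gapOpen + lens * gapExt)
  }
  score - runs(gapA) - runs(gapB)
}

#' Sliding-window divergence profile along a pairwise alignment
#'
#' Computes the p-distance in windows of `windowLength` alignment columns
#' advanced by `step` (150/15 and 450/45 are the conventional settings for
#' short- and long-read screening). Windows where fewer than
#' `minComparableFrac * windowLength` columns are comparable are flagged
#' low-information and carry `NA` instead of a misleading p of 0 — the
#' situation arises where one row is deleted across the window.
#'
#' @param aln a [PairAlignment-class].
#' @param windowLength window width in columns.
#' @param step step between window starts.
#' @param minComparableFrac low-information threshold (default 0.5).
#' @return a [DivergenceProfile-class].
#' @export
slidingProfile <- function(aln, windowLength, step,
                           minComparableFrac = 0.5) {
  by <- .alnBytes(aln)
  L <- length(by$a)
  windowLength <- as.integer(windowLength); step <- as.integer(step)
  if (windowLength > L) stop("windowLength exceeds alignment length")
  comp <- (by$a %in% .ACGT) & (by$b %in% .ACGT)
  mism <- comp & (by$a != by$b)
  cc <- c(0L, cumsum(comp))
  cm <- c(0L, cumsum(mism))
  nWin <- (L - windowLength) %/% step + 1L
  starts <- (seq_len(nWin) - 1L) * step
  nComp <- cc[starts + windowLength + 1L] - cc[starts + 1L]
  nMism <- cm[starts + windowLength + 1L] - cm[starts + 1L]
  lowInfo <- nComp < minComparableFrac * windowLength
  p <- ifelse(lowInfo | nComp == 0L, NA_real_, nMism / nComp)
  new("DivergenceProfile", windowLength = windowLength, step = step,
      windowStarts = as.integer(starts), p = as.numeric(p),
      comparable = as.integer(nComp), lowInfo = lowInfo,
      ids = c(aln@idA, aln@idB))
}

#' Minimum informative window divergence of a profile
#'
#' @param profile a [DivergenceProfile-class].
#' @return smallest p over windows not flagged low-information, or `NA`
#'   when every window is flagged.
#' @export
minWindowDivergence <- function(profile) {
  ok <- !profile@lowInfo & !is.na(profile@p)
  if (!any(ok)) return(NA_real_)
  min(profile@p[ok])
}

#' Write a divergence profile as TSV
#'
#' @param profile a [DivergenceProfile-class].
#' @param path output file.
#' @export
writeProfileTsv <- function(profile, path) {
  df <- data.frame(window_start = profile@windowStarts, p = profile@p,
                   comparable = profile@comparable,
                   low_info = profile@lowInfo)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
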