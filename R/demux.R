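## Sequence-as-tag demultiplexing: assign contigs to taxa via a reference
## marker database, map contigs back to truth genomes, and summarise
## per-genome contig overlap.

#' Build a reference marker database
#'
#' @param taxa taxon label per entry.
#' @param markers marker name per entry (COI, 12S, 16S, CYTB, other).
#' @param seqs ungapped sequences (character vector or
#'   [Biostrings::DNAStringSet]).
#' @param k index k-mer size (default 15; canonical, strand-insensitive).
#' @return a [ReferenceDB-class].
#' @export
referenceDB <- function(taxa, markers, seqs, k = 15L) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(toupper(seqs))
  if (!length(seqs)) stop("reference database must be non-empty")
  idx <- lapply(as.character(seqs), function(s) {
    codes <- cpp_kmer_codes(s, as.integer(k))
    sort(unique(codes[!is.na(codes)]))
  })
  obj <- new("ReferenceDB", taxa = as.character(taxa),
             markers = as.character(markers), seqs = seqs,
             k = as.integer(k), index = idx)
  validObject(obj)
  obj
}

#' Read a reference database from FASTA with "taxon|marker" headers
#'
#' @param path FASTA file; header format `taxon|marker`.
#' @param k index k-mer size.
#' @return a [ReferenceDB-class].
#' @export
readReferenceFasta <- function(path, k = 15L) {
  set <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  parts <- strsplit(ids, "|", fixed = TRUE)
  if (any(lengths(parts) < 2))
    stop("reference FASTA headers must be 'taxon|marker'")
  referenceDB(vapply(parts, `[`, character(1), 1),
              vapply(parts, `[`, character(1), 2), set, k = k)
}

#' Build a COI reference database from annotated genomes
#'
#' Extracts each genome's COI gene (forward orientation) — the usual
#' situation where the pooled specimens were barcoded beforehand.
#'
#' @param genomes list of [AnnotatedMitogenome-class] with COI annotations.
#' @param marker gene to extract (default "COI").
#' @param k index k-mer size.
#' @return a [ReferenceDB-class].
#' @export
referenceFromGenomes <- function(genomes, marker = "COI", k = 15L) {
  seqs <- vapply(genomes, function(g) {
    ann <- g@genes
    hit <- which(ann$name == marker)
    if (!length(hit)) stop("genome '", g@id, "' lacks a ", marker, " annotation")
    s <- sliceCircular(g, ann$start[hit[1]], ann$end[hit[1]])
    if (ann$strand[hit[1]] == "-")
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    s
  }, character(1))
  referenceDB(vapply(genomes, genomeId, character(1)),
              rep(marker, length(genomes)), seqs, k = k)
}

.contigCodes <- function(s, k) {
  codes <- cpp_kmer_codes(s, k)
  codes[!is.na(codes)]
}

#' Assign contigs to taxa by shared-k-mer comparison with the reference DB
#'
#' The score of a contig against a taxon is the largest, over that
#' taxon's markers, fraction of the marker's canonical k-mers found in
#' the contig (strand-insensitive). A contig is `assigned` when its best
#' score reaches `minScore` and exceeds `margin` times the runner-up
#' taxon's score; equal best scores give `ambiguous`; everything else is
#' `unassigned`.
#'
#' @param contigSet a [ContigSet-class] (or [Biostrings::DNAStringSet]).
#' @param refdb a [ReferenceDB-class].
#' @param minScore minimum score to assign (default 0.2).
#' @param margin required dominance over the second-best taxon
#'   (default 2.0).
#' @return data.frame: `contig_id`, `best_taxon`, `best_score`,
#'   `second_taxon`, `second_score`, `status`, `markers_hit`.
#' @export
assignContigs <- function(contigSet, refdb, minScore = 0.2, margin = 2.0) {
  if (!length(refdb@taxa)) stop("empty reference database")
  seqs <- if (is(contigSet, "ContigSet")) contigSet@contigs else contigSet
  taxa <- unique(refdb@taxa)
  out <- lapply(seq_along(seqs), function(ci) {
    codes <- .contigCodes(as.character(seqs[[ci]]), refdb@k)
    entryScore <- vapply(refdb@index, function(ref)
      if (length(ref)) sum(codes %in% ref) / length(ref) else 0, numeric(1))
    taxScore <- vapply(taxa, function(t)
      max(entryScore[refdb@taxa == t]), numeric(1))
    ord <- order(-taxScore, taxa)
    best <- taxScore[ord[1]]
    second <- if (length(taxa) > 1) taxScore[ord[2]] else 0
    status <- if (best >= minScore && best > 0 &&
                  (second == 0 || best >= margin * second)) "assigned"
              else if (best >= minScore && best == second) "ambiguous"
              else if (best >= minScore) "ambiguous"
              else "unassigned"
    hits <- refdb@markers[refdb@taxa == taxa[ord[1]] &
                          entryScore >= minScore]
    data.frame(contig_id = names(seqs)[ci] %||% as.character(ci),
               best_taxon = taxa[ord[1]], best_score = best,
               second_taxon = if (length(taxa) > 1) taxa[ord[2]] else NA_character_,
               second_score = second, status = status,
               markers_hit = paste(hits, collapse = ","),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

.revcompChr <- function(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

#' Map contigs back to their truth genomes
#'
#' Anchors each contig to the doubled sequence of every candidate truth
#' genome with shared 15-mers (canonical, so strand-insensitive), picks
#' the genome with the most anchors, infers strand and placement from
#' the anchor diagonals, and computes base-level identity (exact
#' substring short-cut, else a global-local alignment of the contig
#' against the placed window). Contigs with two or more genomes showing
#' an anchored segment of at least `chimeraSpan` bp at high anchor
#' density are flagged chimeric.
#'
#' @param contigSet a [ContigSet-class].
#' @param truthGenomes list of [AnnotatedMitogenome-class] (or the
#'   mutated haplotypes from a [SimulatedReadSet-class], as
#'   character strings in a named list).
#' @param k anchor k-mer size (default 15).
#' @param chimeraSpan minimum span for a chimeric segment (default 500 bp).
#' @param chimeraDensity minimum anchored k-mer density inside that span
#'   (default 0.2, the score floor used for assignment).
#' @return data.frame with one row per contig: `contig_id`, `genome`,
#'   `start`, `end` (0-based half-open on the circular genome, `end` may
#'   exceed the genome length when the placement wraps), `strand`,
#'   `identity`, `wrapped`, `chimeric`, `n_anchors`.
#' @export
mapContigsToTruth <- function(contigSet, truthGenomes, k = 15L,
                              chimeraSpan = 500L, chimeraDensity = 0.2) {
  seqs <- if (is(contigSet, "ContigSet")) as.character(contigSet@contigs)
          else as.character(contigSet)
  cnames <- names(seqs) %||% as.character(seq_along(seqs))
  gseq <- if (is.list(truthGenomes) && is(truthGenomes[[1]], "AnnotatedMitogenome"))
    setNames(vapply(truthGenomes, function(g) as.character(g@seq), character(1)),
             vapply(truthGenomes, genomeId, character(1)))
  else unlist(truthGenomes)
  gids <- names(gseq)
  L <- nchar(gseq)
  doubled <- vapply(gseq, function(s)
    paste0(s, substr(s, 1, nchar(s) - 1)), character(1))
  gcodes <- lapply(doubled, function(s) cpp_kmer_codes(s, as.integer(k)))
  gsets <- lapply(gcodes, function(cds) unique(cds[!is.na(cds)]))
  rows <- lapply(seq_along(seqs), function(ci) {
    cs <- seqs[ci]
    ccodes <- cpp_kmer_codes(cs, as.integer(k))
    npos <- length(ccodes)
    hitCount <- vapply(seq_along(gids), function(gi)
      sum(ccodes %in% gsets[[gi]], na.rm = TRUE), numeric(1))
    if (all(hitCount == 0))
      return(data.frame(contig_id = cnames[ci], genome = NA_character_,
                        start = NA_integer_, end = NA_integer_,
                        strand = NA_character_, identity = NA_real_,
                        wrapped = FALSE, chimeric = FALSE, n_anchors = 0L))
    ## chimera screen: genomes with a dense anchored segment >= chimeraSpan
    segGenomes <- vapply(seq_along(gids), function(gi) {
      hit <- which(ccodes %in% gsets[[gi]])
      if (length(hit) < 2) return(FALSE)
      span <- max(hit) - min(hit) + k
      dens <- length(hit) / max(1L, span - k + 1L)
      span >= chimeraSpan && dens >= chimeraDensity
    }, logical(1))
    chimeric <- sum(segGenomes) >= 2
    gi <- which.max(hitCount)
    g <- gseq[[gi]]
    Lg <- L[gi]
    ## orientation and placement from anchor positions on the doubled genome
    place <- .placeContig(cs, ccodes, gcodes[[gi]], gsets[[gi]], Lg, k)
    ident <- .placementIdentity(place$orientedSeq, doubled[gi], place$start,
                                nchar(cs), Lg)
    data.frame(contig_id = cnames[ci], genome = gids[gi],
               start = place$start, end = place$end, strand = place$strand,
               identity = ident, wrapped = place$end > Lg,
               chimeric = chimeric, n_anchors = as.integer(hitCount[gi]))
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

## infer strand + placement of one contig on one genome
.placeContig <- function(cs, ccodes, gcode, gset, Lg, k) {
  hit <- which(ccodes %in% gset)
  gpos <- match(ccodes[hit], gcode)        # first occurrence on doubled genome
  ## strand from the direction anchor positions move along the genome
  strand <- "+"
  if (length(hit) >= 2 &&
      isTRUE(median(sign(diff(gpos)), na.rm = TRUE) < 0)) strand <- "-"
  oriented <- if (strand == "-") .revcompChr(cs) else cs
  if (strand == "-") {
    ocodes <- cpp_kmer_codes(oriented, as.integer(k))
    hit <- which(ocodes %in% gset)
    gpos <- match(ocodes[hit], gcode)
  }
  diag <- gpos - hit                        # 0-based genome start estimate
  d <- round(median(diag, na.rm = TRUE))
  start <- (d) %% Lg
  end <- start + nchar(cs)
  list(strand = strand, start = as.integer(start), end = as.integer(end),
       orientedSeq = oriented)
}

## base-level identity of the placed contig against its genome window
.placementIdentity <- function(oriented, doubledG, start, lenC, Lg) {
  ## exact-substring short-cut (typical for exact-read unitigs)
  if (regexpr(oriented, doubledG, fixed = TRUE)[1] != -1) return(1.0)
  pad <- 50L
  from <- max(0L, start - pad)
  to <- min(nchar(doubledG), start + lenC + pad)
  win <- substr(doubledG, from + 1L, to)
  fit <- tryCatch(
    Biostrings::pairwiseAlignment(
      Biostrings::DNAString(oriented), Biostrings::DNAString(win),
      type = "global-local",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
        match = 1, mismatch = -1, baseOnly = FALSE),
      gapOpening = 4, gapExtension = 1),
    error = function(e) NULL)
  if (is.null(fit)) return(NA_real_)
  Biostrings::nmatch(fit) / Biostrings::nchar(fit)
}

#' Per-genome contig overlap summary
#'
#' For each truth genome, reports the best single-contig overlap fraction
#' (largest placement span over the denominator), the circular union of
#' covered bases, and how many contigs exceed each threshold; at the
#' pool level, counts genomes whose best contig overlaps strictly more
#' than each threshold. The denominator is each genome's own length by
#' default; `"fixed_16400"` divides by the 16,400 bp average mitogenome
#' size instead, for comparability with published overlap plots.
#'
#' @param placements data.frame from [mapContigsToTruth()].
#' @param truthGenomes the genomes the placements refer to (list of
#'   [AnnotatedMitogenome-class] or named character vector/list).
#' @param thresholds overlap thresholds in (0,1)
#'   (default `c(1/3, 1/2, 2/3)`).
#' @param denominatorMode "own_length" or "fixed_16400".
#' @return list with `perGenome` (data.frame) and `poolCounts`
#'   (named integer vector, names `gt33`/`gt50`/`gt66` style).
#' @export
overlapSummary <- function(placements, truthGenomes,
                           thresholds = c(1 / 3, 1 / 2, 2 / 3),
                           denominatorMode = c("own_length", "fixed_16400")) {
  denominatorMode <- match.arg(denominatorMode)
  if (any(thresholds <= 0 | thresholds >= 1))
    stop("thresholds must lie in (0,1)")
  gseq <- if (is.list(truthGenomes) && is(truthGenomes[[1]], "AnnotatedMitogenome"))
    setNames(vapply(truthGenomes, function(g) as.character(g@seq), character(1)),
             vapply(truthGenomes, genomeId, character(1)))
  else unlist(truthGenomes)
  gids <- names(gseq)
  L <- nchar(gseq)
  thrNames <- paste0("gt", round(100 * thresholds))
  per <- lapply(seq_along(gids), function(gi) {
    pl <- placements[!is.na(placements$genome) &
                     placements$genome == gids[gi], , drop = FALSE]
    denom <- if (denominatorMode == "own_length") L[gi] else 16400
    if (!nrow(pl)) {
      row <- data.frame(genome = gids[gi], n_contigs = 0L,
                        best_contig = NA_character_, best_fraction = 0,
                        covered_bp = 0L, covered_fraction = 0)
      for (tn in thrNames) row[[paste0("n_contigs_", tn)]] <- 0L
      return(row)
    }
    span <- pmin(pl$end - pl$start, L[gi])
    frac <- span / denom
    bi <- which.max(span)
    cov <- .circularUnion(pl$start, pl$end, L[gi])
    row <- data.frame(genome = gids[gi], n_contigs = nrow(pl),
                      best_contig = pl$contig_id[bi],
                      best_fraction = frac[bi], covered_bp = cov,
                      covered_fraction = cov / L[gi])
    for (ti in seq_along(thresholds))
      row[[paste0("n_contigs_", thrNames[ti])]] <-
        sum(frac > thresholds[ti])
    row
  })
  perGenome <- do.call(rbind, per)
  rownames(perGenome) <- NULL
  poolCounts <- vapply(seq_along(thresholds), function(ti)
    sum(perGenome$best_fraction > thresholds[ti]), integer(1))
  names(poolCounts) <- thrNames
  list(perGenome = perGenome, poolCounts = poolCounts,
       denominatorMode = denominatorMode, thresholds = thresholds)
}

## length of the circular union of [start, end) intervals on a circle of
## circumference L (end may exceed L)
.circularUnion <- function(start, end, L) {
  if (!length(start)) return(0L)
  span <- pmin(end - start, L)
  if (any(span >= L)) return(as.integer(L))
  s <- start %% L
  e <- s + span
  segs <- cbind(s, pmin(e, L))
  wrap <- e > L
  if (any(wrap)) segs <- rbind(segs, cbind(0, e[wrap] - L))
  segs <- segs[order(segs[, 1]), , drop = FALSE]
  tot <- 0
  curS <- segs[1, 1]; curE <- segs[1, 2]
  if (nrow(segs) > 1) for (i in 2:nrow(segs)) {
    if (segs[i, 1] <= curE) curE <- max(curE, segs[i, 2])
    else { tot <- tot + curE - curS; curS <- segs[i, 1]; curE <- segs[i, 2] }
  }
  tot <- tot + curE - curS
  as.integer(min(tot, L))
}

#' Tetranucleotide frequency profile
#'
#' Sliding tetramer counts normalised to sum 1 — the composition signal
#' once examined (and found weakly structuring) as an additional
#' demultiplexing cue for mitogenome pools.
#'
#' @param sequence character string or [Biostrings::DNAString],
#'   length >= 4.
#' @return named numeric vector of 256 tetranucleotide frequencies.
#' @export
tetraProfile <- function(sequence) {
  if (is.character(sequence)) sequence <- Biostrings::DNAString(toupper(sequence))
  if (length(sequence) < 4) stop("sequence must be at least 4 bp")
  counts <- Biostrings::oligonucleotideFrequency(sequence, width = 4)
  total <- sum(counts)
  if (total == 0) stop("no countable tetramers (ambiguous bases?)")
  counts / total
}
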