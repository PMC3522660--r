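## Deterministic de Bruijn unitig baseline assembler.

.readStrings <- function(reads) {
  if (is(reads, "SimulatedReadSet")) as.character(reads@reads)
  else if (is(reads, "DNAStringSet") || is(reads, "XStringSet"))
    as.character(reads)
  else as.character(reads)
}

#' Count canonical k-mers of a read set
#'
#' Builds the k-mer spectrum underlying the unitig graph: each k-mer is
#' counted under its canonical form (lexicographic minimum of itself and
#' its reverse complement); windows containing non-ACGT characters are
#' skipped. Nodes with abundance below `minCount` are pruned.
#'
#' @param reads a [SimulatedReadSet-class], [Biostrings::DNAStringSet]
#'   or character vector.
#' @param k odd k-mer size, default 31 (at most 31).
#' @param minCount abundance pruning threshold (default 1).
#' @return a [KmerGraph-class].
#' @export
buildKmerGraph <- function(reads, k = 31L, minCount = 1L) {
  k <- as.integer(k)
  if (k %% 2L == 0L) stop("k must be odd")
  rs <- .readStrings(reads)
  if (!length(rs)) stop("reads must be non-empty")
  if (k > min(nchar(rs))) stop("k exceeds the shortest read")
  res <- cpp_count_kmers(rs, k)
  keep <- res$count >= minCount
  new("KmerGraph", k = k, kmers = res$kmer[keep],
      counts = as.integer(res$count[keep]), minCount = as.integer(minCount))
}

.contigSet <- function(res, params) {
  seqs <- Biostrings::DNAStringSet(as.character(res$seq))
  if (length(seqs))
    names(seqs) <- sprintf("contig%05d", seq_along(seqs))
  new("ContigSet", contigs = seqs, abundance = as.numeric(res$abundance),
      circular = as.logical(res$circular), params = params)
}

#' Extract unitigs from a k-mer graph
#'
#' Emits every maximal non-branching path of the canonical de Bruijn
#' graph deterministically (start nodes visited in lexicographic k-mer
#' order; each contig reported in its canonical orientation, output
#' sorted by decreasing length). An isolated simple cycle - the signature
#' of a fully recovered circular genome - is emitted once with
#' `circular = TRUE` and its first/last (k-1)-mers coinciding.
#'
#' @param graph a [KmerGraph-class].
#' @return a [ContigSet-class].
#' @export
unitigs <- function(graph) {
  if (!length(graph@kmers))
    return(.contigSet(list(seq = character(0), abundance = numeric(0),
                           circular = logical(0)),
                      list(k = graph@k, minCount = graph@minCount)))
  res <- cpp_unitigs(graph@kmers, graph@counts, graph@k)
  .contigSet(res, list(k = graph@k, minCount = graph@minCount))
}

#' Assemble reads into unitig contigs
#'
#' Counts canonical k-mers, prunes low-abundance nodes (sequencing-error
#' k-mers are mostly singletons) and emits unitigs. All parameters are
#' recorded in the result.
#'
#' @param reads a [SimulatedReadSet-class], [Biostrings::DNAStringSet] or
#'   character vector of reads.
#' @param k odd k-mer size (default 31).
#' @param minCount abundance pruning threshold; use 1 for exact reads and
#'   at least 2 for error-containing reads (see the package vignette for
#'   how to scale it with coverage).
#' @return a [ContigSet-class].
#' @export
assembleReads <- function(reads, k = 31L, minCount = 2L) {
  k <- as.integer(k)
  if (k %% 2L == 0L) stop("k must be odd")
  rs <- .readStrings(reads)
  params <- list(k = k, minCount = as.integer(minCount))
  if (!length(rs))
    return(.contigSet(list(seq = character(0), abundance = numeric(0),
                           circular = logical(0)), params))
  if (k > min(nchar(rs))) stop("k exceeds the shortest read")
  res <- cpp_assemble(rs, k, as.integer(minCount))
  .contigSet(res, params)
}

#' Write contigs as FASTA with abundance/circularity in headers
#'
#' @param contigSet a [ContigSet-class].
#' @param path output FASTA.
#' @export
writeContigs <- function(contigSet, path) {
  set <- contigSet@contigs
  names(set) <- sprintf("%s abundance=%.2f circular=%s",
                        names(set), contigSet@abundance,
                        ifelse(contigSet@circular, "true", "false"))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read an external contig FASTA for evaluation
#'
#' Adapter for contig sets produced by external assemblers; abundance
#' and circularity are parsed from headers of the form written by
#' [writeContigs()] when present, else default to NA/FALSE.
#'
#' @param path contig FASTA.
#' @return a [ContigSet-class].
#' @export
readContigs <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  hdr <- names(set)
  ab <- suppressWarnings(as.numeric(sub(".*abundance=([0-9.]+).*", "\\1", hdr)))
  ab[!grepl("abundance=", hdr)] <- NA_real_
  circ <- grepl("circular=true", hdr)
  names(set) <- sub("\\s.*$", "", hdr)
  new("ContigSet", contigs = set, abundance = ab, circular = circ,
      params = list(source = path))
}
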