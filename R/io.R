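## Sequence / annotation I/O and circular-coordinate handling.

#' Construct an AnnotatedMitogenome
#'
#' @param id specimen/taxon label.
#' @param seq character string or [Biostrings::DNAString] over A,C,G,T,N.
#' @param circular logical, default TRUE.
#' @param genes data.frame with columns `name`, `start` (0-based inclusive),
#'   `end` (exclusive), `strand`; empty by default.
#' @param source free-text provenance.
#' @return an [AnnotatedMitogenome-class] object.
#' @export
annotatedMitogenome <- function(id, seq, circular = TRUE,
                                genes = emptyGeneTable(), source = "") {
  if (is.character(seq)) seq <- Biostrings::DNAString(toupper(seq))
  obj <- new("AnnotatedMitogenome", id = as.character(id), seq = seq,
             circular = circular, genes = as.data.frame(genes),
             source = source)
  validObject(obj)
  obj
}

#' @rdname annotatedMitogenome
#' @export
emptyGeneTable <- function() {
  data.frame(name = character(), start = integer(), end = integer(),
             strand = character(), stringsAsFactors = FALSE)
}

#' Read mitogenome sequences from a FASTA file
#'
#' Sequences are upper-cased. Characters outside `{A,C,G,T,N,-}` raise an
#' error naming the offending line; gap characters are stripped unless
#' `alignment = TRUE` (for reading externally aligned pairs).
#'
#' @param path FASTA file.
#' @param alignment keep gap columns (returns gapped character strings
#'   via [readAlignedFasta()] semantics) — here gaps are retained in the
#'   sequence slot only after stripping is disabled, so prefer
#'   [readAlignedFasta()] for alignments.
#' @param circular mark genomes as circular (default TRUE).
#' @return list of [AnnotatedMitogenome-class] objects (no gene annotations;
#'   attach them with [attachAnnotations()]).
#' @export
readMitoFasta <- function(path, alignment = FALSE, circular = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0) {
    warning("empty FASTA file: ", path)
    return(list())
  }
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("malformed FASTA '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  seqs <- toupper(as.character(set))
  bad <- grepl("[^ACGTN-]", seqs)
  if (any(bad)) {
    lines <- readLines(path)
    off <- grep("^[^>]", lines)
    badline <- off[grepl("[^ACGTNacgtn-]", lines[off])][1]
    stop(sprintf("invalid sequence character in '%s' (record '%s', line %d)",
                 path, names(set)[bad][1],
                 if (length(badline)) badline else NA_integer_))
  }
  if (!alignment) seqs <- gsub("-", "", seqs, fixed = TRUE)
  ids <- sub("\\s.*$", "", names(set))
  lapply(seq_along(seqs), function(i)
    annotatedMitogenome(ids[i], seqs[i], circular = circular,
                        source = path))
}

#' Read an aligned FASTA with exactly two rows as a PairAlignment
#'
#' @param path aligned FASTA (two records, equal gapped lengths).
#' @return a [PairAlignment-class].
#' @export
readAlignedFasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) != 2)
    stop("expected exactly 2 aligned records, got ", length(set))
  rows <- toupper(as.character(set))
  if (grepl("[^ACGTN-]", paste(rows, collapse = "")))
    stop("aligned FASTA restricted to {A,C,G,T,N,-}")
  ids <- sub("\\s.*$", "", names(set))
  new("PairAlignment", idA = ids[1], idB = ids[2],
      rowA = unname(rows[1]), rowB = unname(rows[2]),
      method = "external", params = list())
}

#' Write mitogenomes (or any named sequences) to FASTA
#'
#' @param genomes list of [AnnotatedMitogenome-class] objects.
#' @param path output file.
#' @export
writeMitoFasta <- function(genomes, path) {
  set <- Biostrings::DNAStringSet(vapply(genomes, function(g)
    as.character(g@seq), character(1)))
  names(set) <- vapply(genomes, genomeId, character(1))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read gene annotations from a 5-column TSV or a GFF3 file
#'
#' The TSV convention is `id  name  start  end  strand` with 1-based
#' inclusive coordinates (converted to the package's 0-based half-open
#' convention on read), matching how GFF3 coordinates are interpreted.
#'
#' @param path annotation file; format guessed from the extension
#'   (".gff"/".gff3" versus anything else) unless `format` is given.
#' @param format "tsv" or "gff3".
#' @return data.frame with columns `id`, `name`, `start`, `end`, `strand`
#'   (0-based half-open).
#' @export
readGeneAnnotations <- function(path, format = c("auto", "tsv", "gff3")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3" else "tsv"
  if (format == "gff3") {
    if (!requireNamespace("rtracklayer", quietly = TRUE) ||
        !requireNamespace("GenomicRanges", quietly = TRUE))
      stop("reading GFF3 requires the rtracklayer package")
    gr <- rtracklayer::import(path, format = "gff3")
    nm <- if (!is.null(gr$Name)) as.character(gr$Name)
          else if (!is.null(gr$ID)) as.character(gr$ID)
          else as.character(gr$type)
    out <- data.frame(
      id = as.character(GenomicRanges::seqnames(gr)),
      name = nm,
      start = as.integer(GenomicRanges::start(gr)) - 1L,
      end = as.integer(GenomicRanges::end(gr)),
      strand = as.character(GenomicRanges::strand(gr)),
      stringsAsFactors = FALSE)
    out$strand[!out$strand %in% c("+", "-")] <- "+"
    return(out)
  }
  tab <- read.delim(path, header = FALSE, comment.char = "#",
                    stringsAsFactors = FALSE)
  if (ncol(tab) < 5) stop("annotation TSV needs 5 columns: id name start end strand")
  data.frame(id = as.character(tab[[1]]), name = as.character(tab[[2]]),
             start = as.integer(tab[[3]]) - 1L, end = as.integer(tab[[4]]),
             strand = as.character(tab[[5]]), stringsAsFactors = FALSE)
}

#' Attach gene annotations to genomes
#'
#' @param genomes list of [AnnotatedMitogenome-class] objects.
#' @param annot annotation data.frame from [readGeneAnnotations()].
#' @return the genome list with `genes` filled in.
#' @export
attachAnnotations <- function(genomes, annot) {
  lapply(genomes, function(g) {
    rows <- annot[annot$id == g@id, c("name", "start", "end", "strand")]
    rownames(rows) <- NULL
    g@genes <- rows
    validObject(g)
    g
  })
}

#' Write gene annotations of a set of genomes as a 5-column TSV
#'
#' Coordinates are written 1-based inclusive (the on-disk convention).
#' @param genomes list of [AnnotatedMitogenome-class] objects.
#' @param path output TSV.
#' @export
writeGeneAnnotations <- function(genomes, path) {
  rows <- do.call(rbind, lapply(genomes, function(g) {
    if (!nrow(g@genes)) return(NULL)
    data.frame(id = g@id, name = g@genes$name, start = g@genes$start + 1L,
               end = g@genes$end, strand = g@genes$strand)
  }))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Extract a (possibly wrap-around) slice of a circular genome
#'
#' Returns `seq[start:end)` in 0-based half-open coordinates; when
#' `end > length` the slice wraps past the origin. At most one full
#' revolution is allowed.
#'
#' @param genome an [AnnotatedMitogenome-class], [Biostrings::DNAString]
#'   or character string.
#' @param start 0-based start, in `[0, length)`.
#' @param end exclusive end, `> start`, with `end - start <= length`.
#' @return character string of length `end - start`.
#' @export
sliceCircular <- function(genome, start, end) {
  s <- if (is(genome, "AnnotatedMitogenome")) as.character(genome@seq)
       else as.character(genome)
  L <- nchar(s)
  if (start < 0 || start >= L) stop("start must lie in [0, length)")
  if (end <= start) stop("end must exceed start")
  if (end - start > L) stop("slice cannot exceed one full revolution")
  if (end <= L) return(substr(s, start + 1, end))
  paste0(substr(s, start + 1, L), substr(s, 1, end - L))
}

#' Rotate (and if needed reverse-complement) a genome so a marker starts at 0
#'
#' Mitogenomes are conventionally linearised with the start of the
#' cytochrome oxidase I gene as the first position. If the marker is
#' annotated on the minus strand the genome is reverse-complemented first,
#' so the marker always reads forward from position 0.
#'
#' @param genome an [AnnotatedMitogenome-class] with a `marker` annotation.
#' @param marker gene name to rotate to (default "COI").
#' @return a rotated [AnnotatedMitogenome-class]; length preserved,
#'   annotations re-mapped.
#' @export
linearizeAtGene <- function(genome, marker = "COI") {
  g <- genome@genes
  hit <- which(g$name == marker)
  if (!length(hit))
    stop("no '", marker, "' annotation on genome '", genome@id,
         "'; rotate manually or supply an annotation")
  hit <- hit[1]
  L <- length(genome@seq)
  if (g$strand[hit] == "-") {
    genome <- reverseComplementGenome(genome)
    g <- genome@genes
    hit <- which(g$name == marker)[1]
  }
  r <- g$start[hit] %% L
  if (r == 0) return(genome)
  rotated <- sliceCircular(genome, r, r + L)
  g$start <- (g$start - r) %% L
  g$end <- g$start + (genome@genes$end - genome@genes$start)
  annotatedMitogenome(genome@id, rotated, circular = genome@circular,
                      genes = g, source = genome@source)
}

#' @rdname linearizeAtGene
#' @export
linearizeAtCoi <- function(genome) linearizeAtGene(genome, "COI")

#' Reverse-complement a genome, re-mapping annotations
#'
#' @param genome an [AnnotatedMitogenome-class].
#' @return the reverse-complemented genome.
#' @export
reverseComplementGenome <- function(genome) {
  L <- length(genome@seq)
  rc <- as.character(Biostrings::reverseComplement(genome@seq))
  g <- genome@genes
  if (nrow(g)) {
    w <- g$end - g$start
    newStart <- (L - g$end) %% L
    g <- data.frame(name = g$name, start = newStart, end = newStart + w,
                    strand = ifelse(g$strand == "+", "-", "+"),
                    stringsAsFactors = FALSE)
  }
  annotatedMitogenome(genome@id, rc, circular = genome@circular, genes = g,
                      source = genome@source)
}
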