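## Central S4 classes. Coordinates are 0-based, half-open throughout the
## package; annotation files using 1-based inclusive coordinates (GFF3,
## simple TSV tables) are converted on read.

#' AnnotatedMitogenome: a circular mitochondrial genome with gene annotations
#'
#' @slot id specimen/taxon label.
#' @slot seq a [Biostrings::DNAString] over A,C,G,T,N.
#' @slot circular logical; complete mitogenomes are circular.
#' @slot genes data.frame with columns `name`, `start` (0-based inclusive),
#'   `end` (exclusive; may exceed the genome length for an origin-spanning
#'   feature before wrap normalisation), `strand` ("+"/"-").
#' @slot source free-text provenance.
#' @export
setClass("AnnotatedMitogenome",
  representation(id = "character", seq = "DNAString", circular = "logical",
                 genes = "data.frame", source = "character"))

setValidity("AnnotatedMitogenome", function(object) {
  msg <- character()
  L <- length(object@seq)
  if (L == 0) msg <- c(msg, "sequence must have length > 0")
  freq <- Biostrings::alphabetFrequency(object@seq)
  bad <- sum(freq) - sum(freq[c("A", "C", "G", "T", "N")])
  if (bad > 0) msg <- c(msg, "sequence characters must be in {A,C,G,T,N}")
  g <- object@genes
  if (nrow(g)) {
    need <- c("name", "start", "end", "strand")
    if (!all(need %in% names(g)))
      msg <- c(msg, "genes must have columns name,start,end,strand")
    else {
      if (any(g$start < 0 | g$start >= L)) msg <- c(msg, "gene start out of range")
      if (any(g$end <= g$start)) msg <- c(msg, "gene end must exceed start")
      if (!all(g$strand %in% c("+", "-"))) msg <- c(msg, "strand must be + or -")
      if (sum(g$name == "COI") > 1) msg <- c(msg, "at most one COI annotation")
    }
  }
  if (length(msg)) msg else TRUE
})

#' PairAlignment: a gapped pairwise alignment of two sequences
#'
#' @slot idA,idB labels of the aligned sequences.
#' @slot rowA,rowB equal-length gapped strings over A,C,G,T,N,-.
#' @slot method "external" (read from an aligned FASTA) or "anchored"
#'   (produced by [alignAnchored()]).
#' @slot params list of alignment parameters recorded for reproducibility.
#' @export
setClass("PairAlignment",
  representation(idA = "character", idB = "character", rowA = "character",
                 rowB = "character", method = "character", params = "list"))

setValidity("PairAlignment", function(object) {
  if (nchar(object@rowA) != nchar(object@rowB))
    return("alignment rows must have equal length")
  if (grepl("[^ACGTN-]", object@rowA) || grepl("[^ACGTN-]", object@rowB))
    return("alignment rows restricted to {A,C,G,T,N,-}")
  TRUE
})

#' DivergenceProfile: sliding-window p-distances along a pairwise alignment
#'
#' @slot windowLength window width in alignment columns (e.g. 150 or 450).
#' @slot step window step in columns (e.g. 15 or 45).
#' @slot windowStarts 0-based first column of each window.
#' @slot p per-window p-distance; `NA` where the window is low-information.
#' @slot comparable per-window count of scored (both-ungapped, non-N) columns.
#' @slot lowInfo logical; windows with fewer comparable columns than
#'   `minComparableFrac * windowLength`, e.g. across a deletion in one row.
#' @slot ids labels of the two aligned sequences.
#' @export
setClass("DivergenceProfile",
  representation(windowLength = "integer", step = "integer",
                 windowStarts = "integer", p = "numeric",
                 comparable = "integer", lowInfo = "logical",
                 ids = "character"))

setValidity("DivergenceProfile", function(object) {
  n <- length(object@windowStarts)
  if (length(object@p) != n || length(object@comparable) != n ||
      length(object@lowInfo) != n)
    return("window vectors must have equal length")
  if (any(!is.na(object@p) & (object@p < 0 | object@p > 1)))
    return("p-distances must lie in [0,1]")
  if (any(object@lowInfo & !is.na(object@p)))
    return("low-information windows must carry NA p")
  TRUE
})

#' CompatPolicy: thresholds deciding which specimen pairs may be pooled
#'
#' Defaults follow the empirical screening rule: pairs whose Folmer COI
#' fragment diverges by more than 15% essentially never show a 450 bp
#' window under 5% divergence anywhere along the mitogenome.
#'
#' @slot coiThreshold minimum Folmer-fragment p-distance (default 0.15).
#' @slot windowThreshold minimum per-window p-distance (default 0.05).
#' @slot windowLength window length the window rule refers to (default 450).
#' @slot mode "proxy_only", "windows_only" or "windows_preferred".
#' @export
setClass("CompatPolicy",
  representation(coiThreshold = "numeric", windowThreshold = "numeric",
                 windowLength = "integer", mode = "character"))

setValidity("CompatPolicy", function(object) {
  if (object@coiThreshold <= 0 || object@coiThreshold >= 1 ||
      object@windowThreshold <= 0 || object@windowThreshold >= 1)
    return("thresholds must lie in (0,1)")
  if (!object@mode %in% c("proxy_only", "windows_only", "windows_preferred"))
    return("unknown policy mode")
  TRUE
})

#' CompatibilityMatrix: pairwise pooling evidence for a set of specimens
#'
#' @slot ids specimen labels.
#' @slot compatible symmetric logical matrix (diagonal FALSE).
#' @slot coiProxy symmetric numeric matrix of Folmer proxies (NA = no data).
#' @slot minWindow symmetric numeric matrix of minimum window divergences.
#' @slot flags symmetric character matrix ("ok", "insufficient data", ...).
#' @slot policy the [CompatPolicy-class] snapshot used.
#' @export
setClass("CompatibilityMatrix",
  representation(ids = "character", compatible = "matrix",
                 coiProxy = "matrix", minWindow = "matrix",
                 flags = "matrix", policy = "CompatPolicy"))

setValidity("CompatibilityMatrix", function(object) {
  n <- length(object@ids)
  if (!all(dim(object@compatible) == c(n, n)))
    return("compatible matrix dimension mismatch")
  if (!isTRUE(all(object@compatible == t(object@compatible))))
    return("compatibility must be symmetric")
  if (any(diag(object@compatible)))
    return("diagonal must be FALSE (a specimen cannot pool with itself)")
  TRUE
})

#' PoolPlan: a set of mutually compatible specimens
#'
#' @slot members specimen labels, sorted.
#' @slot minPairwise smallest pairwise divergence evidence within the pool.
#' @slot policy the policy the pool was built under.
#' @export
setClass("PoolPlan",
  representation(members = "character", minPairwise = "numeric",
                 policy = "CompatPolicy"))

#' SimulatedReadSet: simulated reads with full origin provenance
#'
#' @slot reads a named [Biostrings::DNAStringSet].
#' @slot mate integer: 0 = unpaired, 1/2 = mate index.
#' @slot truth data.frame with one row per read: `read_id`, `origin`
#'   (genome id or "RANDOM"), `start` (0-based on the circular haplotype),
#'   `strand`, `n_subs`, `n_indels`, `wrapped`.
#' @slot haplotypes list of mutated haplotype sequences (character) per
#'   genome id, the actual templates reads were drawn from.
#' @slot params simulation parameters (error model, coverage, seed, ...).
#' @export
setClass("SimulatedReadSet",
  representation(reads = "DNAStringSet", mate = "integer",
                 truth = "data.frame", haplotypes = "list", params = "list"))

setValidity("SimulatedReadSet", function(object) {
  if (length(object@reads) != nrow(object@truth))
    return("truth must cover every read")
  if (length(object@mate) != length(object@reads))
    return("mate vector length mismatch")
  TRUE
})

#' KmerGraph: canonical k-mer abundances underlying the unitig assembler
#'
#' @slot k odd k-mer size.
#' @slot kmers canonical k-mer strings (lexicographically sorted).
#' @slot counts abundance per canonical k-mer (after pruning).
#' @slot minCount the pruning threshold applied.
#' @export
setClass("KmerGraph",
  representation(k = "integer", kmers = "character", counts = "integer",
                 minCount = "integer"))

setValidity("KmerGraph", function(object) {
  if (object@k %% 2L == 0L) return("k must be odd")
  if (length(object@kmers) != length(object@counts))
    return("kmers/counts length mismatch")
  if (length(object@counts) && any(object@counts < object@minCount))
    return("all abundances must be >= minCount after pruning")
  TRUE
})

#' ContigSet: assembled contigs
#'
#' @slot contigs named [Biostrings::DNAStringSet].
#' @slot abundance mean k-mer abundance per contig.
#' @slot circular logical; TRUE when the contig was emitted from an isolated
#'   simple cycle (first and last (k-1)-mers coincide).
#' @slot params assembly parameters (k, minCount, ...).
#' @export
setClass("ContigSet",
  representation(contigs = "DNAStringSet", abundance = "numeric",
                 circular = "logical", params = "list"))

setValidity("ContigSet", function(object) {
  n <- length(object@contigs)
  if (length(object@abundance) != n || length(object@circular) != n)
    return("per-contig vectors must match the number of contigs")
  k <- object@params$k
  if (!is.null(k) && n && any(Biostrings::width(object@contigs) < k))
    return("contigs must be at least k long")
  TRUE
})

#' ReferenceDB: reference marker database for sequence-as-tag demultiplexing
#'
#' @slot taxa taxon label per entry.
#' @slot markers marker name per entry (COI, 12S, 16S, CYTB, other).
#' @slot seqs ungapped [Biostrings::DNAStringSet] of marker sequences.
#' @slot k k-mer size of the index (default 15).
#' @slot index list of integer vectors: unique canonical k-mer codes per entry.
#' @export
setClass("ReferenceDB",
  representation(taxa = "character", markers = "character",
                 seqs = "DNAStringSet", k = "integer", index = "list"))

setValidity("ReferenceDB", function(object) {
  n <- length(object@taxa)
  if (length(object@markers) != n || length(object@seqs) != n ||
      length(object@index) != n)
    return("per-entry slots must have equal length")
  if (anyDuplicated(paste(object@taxa, object@markers)))
    return("(taxon, marker) pairs must be unique")
  TRUE
})
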