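#' @name mitopool-accessors
#' @title Accessors for mitopool classes
#' @description Small accessor generics so user code never touches slots.
#' @param x an object.
#' @param object an object (for `show`).
NULL

#' @rdname mitopool-accessors
#' @export
setGeneric("genomeId", function(x) standardGeneric("genomeId"))
#' @rdname mitopool-accessors
#' @export
setGeneric("genomeSeq", function(x) standardGeneric("genomeSeq"))
#' @rdname mitopool-accessors
#' @export
setGeneric("genes", function(x) standardGeneric("genes"))
#' @rdname mitopool-accessors
#' @export
setGeneric("isCircular", function(x) standardGeneric("isCircular"))
#' @rdname mitopool-accessors
#' @export
setGeneric("poolMembers", function(x) standardGeneric("poolMembers"))
#' @rdname mitopool-accessors
#' @export
setGeneric("contigs", function(x) standardGeneric("contigs"))
#' @rdname mitopool-accessors
#' @export
setGeneric("truth", function(x) standardGeneric("truth"))
#' @rdname mitopool-accessors
#' @export
setGeneric("simReads", function(x) standardGeneric("simReads"))

#' @rdname mitopool-accessors
#' @export
setMethod("genomeId", "AnnotatedMitogenome", function(x) x@id)
#' @rdname mitopool-accessors
#' @export
setMethod("genomeSeq", "AnnotatedMitogenome", function(x) x@seq)
#' @rdname mitopool-accessors
#' @export
setMethod("genes", "AnnotatedMitogenome", function(x) x@genes)
#' @rdname mitopool-accessors
#' @export
setMethod("isCircular", "AnnotatedMitogenome", function(x) x@circular)
#' @rdname mitopool-accessors
#' @export
setMethod("poolMembers", "PoolPlan", function(x) x@members)
#' @rdname mitopool-accessors
#' @export
setMethod("contigs", "ContigSet", function(x) x@contigs)
#' @rdname mitopool-accessors
#' @export
setMethod("truth", "SimulatedReadSet", function(x) x@truth)
#' @rdname mitopool-accessors
#' @export
setMethod("simReads", "SimulatedReadSet", function(x) x@reads)

#' @export
setMethod("length", "AnnotatedMitogenome", function(x) length(x@seq))
#' @export
setMethod("length", "ContigSet", function(x) length(x@contigs))
#' @export
setMethod("length", "SimulatedReadSet", function(x) length(x@reads))

#' @rdname mitopool-accessors
#' @export
setMethod("show", "AnnotatedMitogenome", function(object) {
  cat(sprintf("AnnotatedMitogenome '%s': %d bp, %s, %d gene(s)\n",
              object@id, length(object@seq),
              if (object@circular) "circular" else "linear",
              nrow(object@genes)))
})

#' @rdname mitopool-accessors
#' @export
setMethod("show", "PairAlignment", function(object) {
  cat(sprintf("PairAlignment %s vs %s: %d columns (%s)\n",
              object@idA, object@idB, nchar(object@rowA), object@method))
})

#' @rdname mitopool-accessors
#' @export
setMethod("show", "DivergenceProfile", function(object) {
  ok <- !object@lowInfo
  cat(sprintf(
    "DivergenceProfile %s vs %s: window %d bp / step %d bp, %d windows (%d low-info)\n",
    object@ids[1], object@ids[2], object@windowLength, object@step,
    length(object@p), sum(object@lowInfo)))
  if (any(ok))
    cat(sprintf("  p-distance: min %.4f / median %.4f / max %.4f\n",
                min(object@p[ok]), median(object@p[ok]), max(object@p[ok])))
})

#' @rdname mitopool-accessors
#' @export
setMethod("show", "CompatibilityMatrix", function(object) {
  n <- length(object@ids)
  np <- n * (n - 1) / 2
  ut <- upper.tri(object@compatible)
  cat(sprintf("CompatibilityMatrix: %d specimens, %d/%d pairs compatible (mode %s)\n",
              n, sum(object@compatible[ut]), np, object@policy@mode))
})

#' @rdname mitopool-accessors
#' @export
setMethod("show", "PoolPlan", function(object) {
  cat(sprintf("PoolPlan: %d member(s) [%s], min pairwise evidence %.4f\n",
              length(object@members), paste(object@members, collapse = ", "),
              object@minPairwise))
})

#' @rdname mitopool-accessors
#' @export
setMethod("show", "SimulatedReadSet", function(object) {
  nr <- length(object@reads)
  nrand <- sum(object@truth$origin == "RANDOM")
  cat(sprintf("SimulatedReadSet: %d reads (%d random/contaminant), %s\n",
              nr, nrand,
              if (any(object@mate > 0L)) "paired-end" else "single-end"))
})

#' @rdname mitopool-accessors
#' @export
setMethod("show", "KmerGraph", function(object) {
  cat(sprintf("KmerGraph: k=%d, %d canonical k-mers (minCount %d)\n",
              object@k, length(object@kmers), object@minCount))
})

#' @rdname mitopool-accessors
#' @export
setMethod("show", "ContigSet", function(object) {
  w <- Biostrings::width(object@contigs)
  cat(sprintf("ContigSet: %d contig(s), total %d bp, longest %d bp, %d circular\n",
              length(w), sum(w), if (length(w)) max(w) else 0L,
              sum(object@circular)))
})

#' @rdname mitopool-accessors
#' @export
setMethod("show", "ReferenceDB", function(object) {
  cat(sprintf("ReferenceDB: %d entries, %d taxa, markers: %s (k=%d)\n",
              length(object@taxa), length(unique(object@taxa)),
              paste(sort(unique(object@markers)), collapse = ", "), object@k))
})
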