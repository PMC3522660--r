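## Synthetic mitogenome-family generator: an ancestor with a realistic
## gene mosaic, evolved descendants with region-specific substitution
## rates, so pool design / simulation / demultiplexing are testable on
## fully controlled inputs.

#' Region model of a metazoan mitogenome
#'
#' An ordered gene layout (~15.7 kb: 13 protein-coding genes with a
#' 1,545 bp COI first, 2 rRNAs, 22 tRNAs interleaved, one control
#' region) plus per-class substitution-rate multipliers capturing the
#' alternation of variable and conserved regions: rRNAs are the most
#' conserved segments, tRNAs intermediate, protein-coding genes the
#' reference rate, and the control region the fastest.
#'
#' @param rateMultipliers named numeric vector for classes PCG, rRNA,
#'   tRNA, CR (defaults 1.0, 0.3, 0.5, 2.0).
#' @param layout optional data.frame (`name`, `length`, `class`) to
#'   override the default gene order.
#' @return list of class `RegionModel` with `layout` and `rateMultipliers`.
#' @export
regionModel <- function(rateMultipliers = c(PCG = 1.0, rRNA = 0.3,
                                            tRNA = 0.5, CR = 2.0),
                        layout = NULL) {
  if (any(rateMultipliers <= 0)) stop("rate multipliers must be positive")
  if (is.null(layout)) layout <- .defaultLayout()
  if (any(layout$length <= 0)) stop("region lengths must be positive")
  if (!"COI" %in% layout$name) stop("layout must include a COI gene")
  if (!all(layout$class %in% names(rateMultipliers)))
    stop("every region class needs a rate multiplier")
  structure(list(layout = layout, rateMultipliers = rateMultipliers),
            class = "RegionModel")
}

## vertebrate-flavoured order: COI first (the linearisation convention),
## tRNAs interleaved between genes, rRNA block, control region last
.defaultLayout <- function() {
  pcg <- c(COI = 1545, COII = 688, ATP8 = 168, ATP6 = 681, COIII = 784,
           ND3 = 349, ND4L = 297, ND4 = 1378, ND5 = 1812, ND6 = 522,
           CYTB = 1141, ND1 = 975, ND2 = 1044)
  rrna <- c(`12S` = 820, `16S` = 1400)
  ## interleave two tRNAs after every PCG except the last few, then a
  ## cluster near the rRNAs (22 total)
  regions <- list()
  trnaCount <- 0
  addTrna <- function(n) {
    out <- list()
    for (i in seq_len(n)) {
      trnaCount <<- trnaCount + 1
      out[[i]] <- data.frame(name = sprintf("tRNA%02d", trnaCount),
                             length = 68L, class = "tRNA")
    }
    do.call(rbind, out)
  }
  rows <- list()
  for (i in seq_along(pcg)) {
    rows[[length(rows) + 1]] <- data.frame(name = names(pcg)[i],
                                           length = unname(pcg[i]),
                                           class = "PCG")
    if (trnaCount < 18) rows[[length(rows) + 1]] <- addTrna(ifelse(i %% 2, 1, 2))
  }
  rows[[length(rows) + 1]] <- data.frame(name = "12S", length = 820L,
                                         class = "rRNA")
  rows[[length(rows) + 1]] <- addTrna(1)
  rows[[length(rows) + 1]] <- data.frame(name = "16S", length = 1400L,
                                         class = "rRNA")
  rows[[length(rows) + 1]] <- addTrna(22 - trnaCount - 0)
  rows[[length(rows) + 1]] <- data.frame(name = "CR", length = 650L,
                                         class = "CR")
  layout <- do.call(rbind, rows)
  rownames(layout) <- NULL
  layout
}

#' Family specification for the synthetic generator
#'
#' @param nTaxa number of descendant genomes (star phylogeny).
#' @param targetDivergence genome-wide mean p-distance of each descendant
#'   versus the ancestor, in (0, 0.35].
#' @param indelRate short-indel rate per site (default 1e-4; indels never
#'   fall inside the Folmer COI window so the barcode proxy stays
#'   well-defined).
#' @param seed integer seed.
#' @return list of class `FamilySpec`.
#' @export
familySpec <- function(nTaxa, targetDivergence, indelRate = 1e-4, seed = 1L) {
  if (nTaxa < 1) stop("nTaxa must be >= 1")
  if (targetDivergence <= 0 || targetDivergence > 0.35)
    stop("targetDivergence must lie in (0, 0.35]")
  structure(list(nTaxa = as.integer(nTaxa),
                 targetDivergence = targetDivergence,
                 indelRate = indelRate, seed = as.integer(seed)),
            class = "FamilySpec")
}

.geneTableFromLayout <- function(layout) {
  ends <- cumsum(layout$length)
  starts <- c(0L, utils::head(ends, -1))
  data.frame(name = layout$name, start = as.integer(starts),
             end = as.integer(ends),
             strand = "+", stringsAsFactors = FALSE)
}

#' Generate a random ancestral mitogenome
#'
#' Uniform-random sequence per region, annotated and circular, COI at
#' position 0. Seeds whose sequence contains a duplicated 31-mer are
#' rejected and resampled (repeats would confound the unitig assembler's
#' baseline guarantees).
#'
#' @param model a [regionModel()].
#' @param seed integer seed.
#' @param maxTries rejection-sampling limit (default 20).
#' @return an [AnnotatedMitogenome-class] with id "ancestor".
#' @export
makeAncestor <- function(model = regionModel(), seed = 1L, maxTries = 20L) {
  L <- sum(model$layout$length)
  genes <- .geneTableFromLayout(model$layout)
  for (try in seq_len(maxTries)) {
    s <- withr::with_seed(as.integer(seed) + (try - 1L) * 1000003L,
                          .randomDna(L))
    circ <- paste0(s, substr(s, 1, 30))
    km <- cpp_count_kmers(circ, 31L)
    if (max(km$count) == 1L)
      return(annotatedMitogenome("ancestor", s, circular = TRUE,
                                 genes = genes,
                                 source = sprintf("synthetic seed=%d", seed)))
  }
  stop("could not draw a 31-mer-repeat-free ancestor in ", maxTries, " tries")
}

#' Evolve a descendant at a controlled divergence
#'
#' Per region, places `round(length * target * multiplier / weightedMean)`
#' substitutions at distinct uniform sites (each changed to a different
#' base), so the realised per-region p-distance versus the ancestor is
#' exact before indels. Short indels (1-10 bp, geometric length) are then
#' applied at `indelRate` per site, never inside the Folmer COI window
#' (positions 50-700 of COI), and annotations are re-mapped.
#'
#' @param ancestor the [makeAncestor()] genome (COI at position 0).
#' @param targetDivergence genome-wide mean p-distance versus the ancestor.
#' @param model the [regionModel()] used to build the ancestor.
#' @param indelRate per-site indel rate (default 0).
#' @param seed integer seed.
#' @param id label for the descendant.
#' @return an [AnnotatedMitogenome-class].
#' @export
evolve <- function(ancestor, targetDivergence, model = regionModel(),
                   indelRate = 0, seed = 1L, id = "descendant") {
  layout <- model$layout
  mult <- model$rateMultipliers[layout$class]
  wmean <- sum(layout$length * mult) / sum(layout$length)
  perRegionP <- targetDivergence * mult / wmean
  if (any(perRegionP > 0.75))
    stop("implied per-region divergence exceeds 0.75; lower the target")
  chars <- strsplit(as.character(ancestor@seq), "")[[1]]
  ends <- cumsum(layout$length)
  starts <- c(0L, utils::head(ends, -1))
  withr::with_seed(as.integer(seed), {
    for (r in seq_len(nrow(layout))) {
      nsub <- round(layout$length[r] * perRegionP[r])
      if (nsub == 0) next
      sites <- starts[r] + sample.int(layout$length[r], nsub)
      for (p in sites) chars[p] <- sample(setdiff(.BASES, chars[p]), 1)
    }
  })
  mutated <- paste(chars, collapse = "")
  genes <- ancestor@genes
  if (indelRate > 0) {
    L <- nchar(mutated)
    coi <- genes[genes$name == "COI", ]
    folmer <- c(coi$start + 49L, coi$start + 700L)   # 0-based half-open
    withr::with_seed(as.integer(seed) + 1L, {
      nIndel <- rbinom(1L, L, indelRate)
      if (nIndel > 0) {
        pos <- sort(sample.int(L, nIndel))
        pos <- pos[pos <= folmer[1] | pos > folmer[2]]
        lens <- pmin(1L + stats::rgeom(length(pos), 0.7), 10L)
        ins <- runif(length(pos)) < 0.5
        cv <- strsplit(mutated, "")[[1]]
        for (r in rev(seq_along(pos))) {
          p <- pos[r]
          if (ins[r]) {
            cv <- append(cv, sample(.BASES, lens[r], replace = TRUE),
                         after = p)
          } else {
            delTo <- min(p + lens[r] - 1L, length(cv))
            cv <- cv[-(p:delTo)]
          }
        }
        ## re-map annotations through the offsets; widths kept nominal so
        ## marker extraction windows stay comparable across the family
        delta <- ifelse(ins, lens, -lens)
        shift <- function(b) b + sum(delta[pos - 1L < b])
        w <- genes$end - genes$start
        mutated <- paste(cv, collapse = "")
        newL <- nchar(mutated)
        genes$start <- pmax(0L, pmin(as.integer(vapply(genes$start, shift,
                                                       numeric(1))),
                                     newL - 1L))
        genes$end <- genes$start + w
      }
    })
  }
  annotatedMitogenome(id, mutated, circular = TRUE, genes = genes,
                      source = sprintf("evolved target=%g seed=%d",
                                       targetDivergence, seed))
}

#' Generate a synthetic mitogenome family
#'
#' Independent draws of [evolve()] from a single ancestor (star
#' phylogeny). Substitutions are placed at distinct sites per branch, so a
#' site hit on both branches still differs between the two descendants
#' with probability 2/3; two descendants at ancestor-divergence `t` are
#' therefore expected to differ pairwise by about `2 t (1 - 2 t / 3)`
#' genome-wide. Measured Folmer COI proxies for every pair are written to
#' the truth table.
#'
#' @param spec a [familySpec()].
#' @param model a [regionModel()].
#' @return list with `genomes` (list of [AnnotatedMitogenome-class],
#'   ids "T01", "T02", ...), `ancestor`, and `truth` (data.frame of
#'   pairwise Folmer proxies and the expected pairwise p).
#' @export
makeFamily <- function(spec, model = regionModel()) {
  anc <- makeAncestor(model, seed = spec$seed)
  subSeeds <- withr::with_seed(spec$seed + 1L,
                               sample.int(.Machine$integer.max - 2L,
                                          spec$nTaxa))
  genomes <- lapply(seq_len(spec$nTaxa), function(i)
    evolve(anc, spec$targetDivergence, model, indelRate = spec$indelRate,
           seed = subSeeds[i], id = sprintf("T%02d", i)))
  t <- spec$targetDivergence
  expectedPairP <- 2 * t * (1 - 2 * t / 3)
  truth <- NULL
  if (spec$nTaxa >= 2) {
    pairs <- combn(spec$nTaxa, 2)
    truth <- data.frame(
      idA = sprintf("T%02d", pairs[1, ]), idB = sprintf("T%02d", pairs[2, ]),
      folmer_proxy = apply(pairs, 2, function(pr)
        folmerProxy(genomes[[pr[1]]], genomes[[pr[2]]])),
      expected_pairwise_p = expectedPairP)
  }
  list(genomes = genomes, ancestor = anc, truth = truth,
       spec = spec, model = model)
}
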