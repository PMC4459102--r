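# Central S4 classes. Coordinates are 0-based half-open internally and
# 1-based in user-facing reports.

#' Reference genome with optional feature annotations
#'
#' Holds a (typically circular) mitochondrial reference sequence together
#' with named feature intervals such as the D-loop control region or the
#' cytochrome-b gene.
#'
#' @slot id single identifier string.
#' @slot sequence a [Biostrings::DNAString] over A/C/G/T.
#' @slot circular logical; circular molecules allow fragments to wrap the
#'   origin.
#' @slot annotations data.frame with columns `name`, `start`, `end`
#'   (0-based, half-open).
#'
#' @exportClass ReferenceGenome
setClass("ReferenceGenome",
  representation(id = "character", sequence = "DNAString",
                 circular = "logical", annotations = "data.frame"),
  validity = function(object) {
    msg <- character()
    L <- length(object@sequence)
    if (L < 1) msg <- c(msg, "sequence must be non-empty")
    if (!all(strsplit(as.character(object@sequence), "")[[1]] %in%
             c("A", "C", "G", "T")))
      msg <- c(msg, "sequence alphabet restricted to A/C/G/T")
    a <- object@annotations
    if (nrow(a)) {
      if (!all(c("name", "start", "end") %in% names(a)))
        msg <- c(msg, "annotations need columns name, start, end")
      else if (any(a$start < 0) || any(a$end > L) || any(a$end <= a$start))
        msg <- c(msg, "annotation intervals must lie within [0, length)")
    }
    if (length(msg)) msg else TRUE
  })

#' @describeIn ReferenceGenome-class constructor.
#' @param id,sequence,circular,annotations see slots.
#' @export
ReferenceGenome <- function(id, sequence, circular = TRUE,
                            annotations = data.frame(
                              name = character(), start = integer(),
                              end = integer())) {
  if (is.character(sequence)) sequence <- Biostrings::DNAString(sequence)
  new("ReferenceGenome", id = id, sequence = sequence,
      circular = circular, annotations = annotations)
}

setMethod("show", "ReferenceGenome", function(object) {
  cat("ReferenceGenome", object@id, "-", length(object@sequence), "bp,",
      if (object@circular) "circular" else "linear", "\n")
  if (nrow(object@annotations))
    cat("  annotations:", paste(object@annotations$name, collapse = ", "),
        "\n")
})

#' Briggs-type post-mortem deamination model
#'
#' Parameters of overhang-restricted cytosine deamination: each fragment end
#' carries a geometric single-stranded overhang (position p from the end is
#' single-stranded with probability `overhangDecay^p`), cytosines deaminate
#' at rate `deltaSS` inside overhangs and `deltaDS` in the double-stranded
#' interior. With `bothStrands = TRUE` (double-strand library protocol) both
#' strands of each molecule are sequenced, which caps the observable
#' 5'-terminal C-to-T frequency at 50%.
#'
#' @slot overhangDecay geometric overhang decay parameter in (0, 1].
#' @slot deltaSS single-stranded deamination probability.
#' @slot deltaDS residual double-stranded deamination probability.
#' @slot bothStrands logical, double-strand library protocol flag.
#'
#' @exportClass DamageModel
setClass("DamageModel",
  representation(overhangDecay = "numeric", deltaSS = "numeric",
                 deltaDS = "numeric", bothStrands = "logical"),
  validity = function(object) {
    p <- c(object@overhangDecay, object@deltaSS, object@deltaDS)
    if (any(p < 0 | p > 1)) "all probabilities must lie in [0, 1]" else TRUE
  })

#' @describeIn DamageModel-class constructor.
#' @param overhangDecay,deltaSS,deltaDS,bothStrands see slots.
#' @export
DamageModel <- function(overhangDecay = 0.5, deltaSS = 0.9, deltaDS = 0.01,
                        bothStrands = TRUE) {
  new("DamageModel", overhangDecay = overhangDecay, deltaSS = deltaSS,
      deltaDS = deltaDS, bothStrands = bothStrands)
}

setMethod("show", "DamageModel", function(object) {
  cat(sprintf(
    "DamageModel: overhang decay %.3g, deltaSS %.3g, deltaDS %.3g, %s\n",
    object@overhangDecay, object@deltaSS, object@deltaDS,
    if (object@bothStrands) "double-strand protocol"
    else "single-strand protocol"))
  cat(sprintf("  expected 5'-terminal C->T frequency: %.1f%%\n",
              100 * expectedTerminalFrequency(object, 1)))
})

#' Fragment length / coverage model for library simulation
#'
#' Fragment lengths are drawn as `minLength` plus a negative-binomial
#' variate with mean `meanLength - minLength` and size `dispersion`, so the
#' empirical mean length matches `meanLength`.
#'
#' @slot meanLength mean fragment length (bp).
#' @slot dispersion negative-binomial size parameter.
#' @slot minLength minimum fragment length (bp).
#' @slot coverageTarget target fold-coverage of the reference.
#'
#' @exportClass FragmentationModel
setClass("FragmentationModel",
  representation(meanLength = "numeric", dispersion = "numeric",
                 minLength = "numeric", coverageTarget = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@minLength < 1) msg <- c(msg, "minLength must be >= 1")
    if (object@meanLength < object@minLength)
      msg <- c(msg, "meanLength must be >= minLength")
    if (length(msg)) msg else TRUE
  })

#' @describeIn FragmentationModel-class constructor.
#' @param meanLength,dispersion,minLength,coverageTarget see slots.
#' @export
FragmentationModel <- function(meanLength = 60, dispersion = 6,
                               minLength = 30, coverageTarget = 30) {
  new("FragmentationModel", meanLength = meanLength, dispersion = dispersion,
      minLength = minLength, coverageTarget = coverageTarget)
}

#' Read-pair merging parameters
#'
#' Defaults follow the standard ancient-DNA processing choices: mates are
#' merged when they overlap by at least 11 bp and merged reads shorter than
#' 30 bp are discarded.
#'
#' @slot minOverlap minimum overlap (bp) to accept a merge.
#' @slot minLength minimum merged-read length (bp) to retain.
#' @slot maxMismatchFraction maximum mismatch fraction within the overlap.
#'
#' @exportClass MergeParams
setClass("MergeParams",
  representation(minOverlap = "numeric", minLength = "numeric",
                 maxMismatchFraction = "numeric"),
  validity = function(object) {
    if (object@minOverlap < 1 || object@minLength < 1)
      "minOverlap and minLength must be >= 1" else TRUE
  })

#' @describeIn MergeParams-class constructor.
#' @param minOverlap,minLength,maxMismatchFraction see slots.
#' @export
MergeParams <- function(minOverlap = 11, minLength = 30,
                        maxMismatchFraction = 0.1) {
  new("MergeParams", minOverlap = minOverlap, minLength = minLength,
      maxMismatchFraction = maxMismatchFraction)
}

#' Consensus-calling parameters
#'
#' @slot minCoverage minimum unique-read depth to call a base (default 3;
#'   positions below it are reported as N).
#' @slot majorityFraction minimum fraction of the pileup the winning base
#'   must reach.
#' @slot maxIterations cap on map-to-consensus iterations.
#'
#' @exportClass ConsensusParams
setClass("ConsensusParams",
  representation(minCoverage = "numeric", majorityFraction = "numeric",
                 maxIterations = "numeric"),
  validity = function(object) {
    if (object@minCoverage < 1) "minCoverage must be >= 1" else TRUE
  })

#' @describeIn ConsensusParams-class constructor.
#' @param minCoverage,majorityFraction,maxIterations see slots.
#' @export
ConsensusParams <- function(minCoverage = 3, majorityFraction = 0.5,
                            maxIterations = 10) {
  new("ConsensusParams", minCoverage = minCoverage,
      majorityFraction = majorityFraction, maxIterations = maxIterations)
}

#' Result of iterative reference-guided assembly
#'
#' @slot consensus [Biostrings::DNAString] over A/C/G/T/N; sub-threshold
#'   positions are N.
#' @slot coverage integer vector of unique-read depth per reference position.
#' @slot uniqueFragments number of unique mapped fragments after duplicate
#'   removal.
#' @slot iterations number of map-consensus rounds used.
#' @slot fractionCovered fraction of positions with depth >= minCoverage.
#' @slot alignments data.frame of the final unique alignments.
#' @slot failed logical; TRUE when no reads mapped in round 1.
#'
#' @exportClass AssemblyResult
setClass("AssemblyResult",
  representation(consensus = "DNAString", coverage = "integer",
                 uniqueFragments = "integer", iterations = "integer",
                 fractionCovered = "numeric", alignments = "data.frame",
                 failed = "logical"))

setMethod("show", "AssemblyResult", function(object) {
  if (object@failed) {
    cat("AssemblyResult: assembly failed (no reads mapped)\n")
    return(invisible(NULL))
  }
  cat(sprintf(
    "AssemblyResult: %d bp consensus, %d unique fragments, %d iteration(s)\n",
    length(object@consensus), object@uniqueFragments, object@iterations))
  cat(sprintf("  %.2f%% of positions at >= threshold coverage, mean unique coverage %.1fx\n",
              100 * object@fractionCovered, mean(object@coverage)))
})

#' @rdname AssemblyResult-class
#' @param object,x an `AssemblyResult`.
#' @export
setGeneric("consensusSeq", function(x) standardGeneric("consensusSeq"))
#' @rdname AssemblyResult-class
#' @export
setMethod("consensusSeq", "AssemblyResult", function(x) x@consensus)
#' @rdname AssemblyResult-class
#' @export
setGeneric("coverageTrack", function(x) standardGeneric("coverageTrack"))
#' @rdname AssemblyResult-class
#' @export
setMethod("coverageTrack", "AssemblyResult", function(x) x@coverage)
#' @rdname AssemblyResult-class
#' @export
setGeneric("uniqueFragments", function(x) standardGeneric("uniqueFragments"))
#' @rdname AssemblyResult-class
#' @export
setMethod("uniqueFragments", "AssemblyResult", function(x) x@uniqueFragments)

#' Positional terminal misincorporation table
#'
#' Substitution counts and conditional frequencies (count of X-to-Y at
#' position p divided by the number of aligned reference-X opportunities at
#' p) for the first K positions from the read 5' and 3' ends.
#'
#' @slot table data.frame with columns `end` ("5p"/"3p"), `position`,
#'   `sub` (e.g. "C>T"), `count`, `opportunities`, `frequency`.
#' @slot K number of terminal positions profiled.
#'
#' @exportClass MisincorporationTable
setClass("MisincorporationTable",
  representation(table = "data.frame", K = "integer"),
  validity = function(object) {
    tab <- object@table
    ok <- all(tab$count <= tab$opportunities)
    f <- tab$frequency[!is.na(tab$frequency)]
    if (!ok || any(f < 0 | f > 1))
      "counts must not exceed opportunities and frequencies must lie in [0,1]"
    else TRUE
  })

setMethod("show", "MisincorporationTable", function(object) {
  cat("MisincorporationTable over", object@K, "terminal positions\n")
  ct <- terminalFrequency(object, "5p", "C>T")
  ga <- terminalFrequency(object, "3p", "G>A")
  cat(sprintf("  5' C->T position 1: %s   3' G->A position 1: %s\n",
              ifelse(is.na(ct), "undefined", sprintf("%.1f%%", 100 * ct)),
              ifelse(is.na(ga), "undefined", sprintf("%.1f%%", 100 * ga))))
})

#' Ancient-DNA authenticity verdict
#'
#' Conjunctive rule on terminal substitution frequencies: a library is
#' regarded as authentic ancient DNA when both the 5'-terminal C-to-T and
#' the 3'-terminal G-to-A frequency reach the threshold (default 20%).
#'
#' @slot c2t5prime 5'-terminal (position 1) C-to-T frequency.
#' @slot g2a3prime 3'-terminal (position 1) G-to-A frequency.
#' @slot threshold authentication threshold (default 0.20).
#' @slot authentic logical; NA when a terminal frequency is undefined
#'   (verdict indeterminate).
#'
#' @exportClass AuthenticationVerdict
setClass("AuthenticationVerdict",
  representation(c2t5prime = "numeric", g2a3prime = "numeric",
                 threshold = "numeric", authentic = "logical"))

setMethod("show", "AuthenticationVerdict", function(object) {
  v <- if (is.na(object@authentic)) "indeterminate"
       else if (object@authentic) "authentic ancient DNA"
       else "not authentic"
  cat(sprintf(
    "AuthenticationVerdict: %s (5' C->T %.1f%%, 3' G->A %.1f%%, threshold %.0f%%)\n",
    v, 100 * object@c2t5prime, 100 * object@g2a3prime,
    100 * object@threshold))
})

#' @rdname AuthenticationVerdict-class
#' @param x an `AuthenticationVerdict`.
#' @export
setGeneric("isAuthentic", function(x) standardGeneric("isAuthentic"))
#' @rdname AuthenticationVerdict-class
#' @export
setMethod("isAuthentic", "AuthenticationVerdict", function(x) x@authentic)

#' GTR+G+I substitution model
#'
#' General time-reversible nucleotide model with discrete-gamma rate
#' heterogeneity (equal-probability categories, mean-of-quantile rates) and
#' a proportion of invariant sites. Variable-category rates are rescaled by
#' 1/(1 - pInvariant) so the overall mean rate is exactly 1.
#'
#' @slot rates named numeric(6) exchangeabilities (AC, AG, AT, CG, CT, GT).
#' @slot baseFreqs named numeric(4) stationary frequencies (A, C, G, T).
#' @slot gammaShape gamma shape parameter alpha (default 0.3366).
#' @slot nCategories number of gamma categories (default 5).
#' @slot pInvariant proportion of invariant sites.
#'
#' @exportClass PhyloModel
setClass("PhyloModel",
  representation(rates = "numeric", baseFreqs = "numeric",
                 gammaShape = "numeric", nCategories = "numeric",
                 pInvariant = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@rates) != 6 || any(object@rates <= 0))
      msg <- c(msg, "need 6 positive exchangeabilities")
    if (length(object@baseFreqs) != 4 ||
        abs(sum(object@baseFreqs) - 1) > 1e-8 || any(object@baseFreqs <= 0))
      msg <- c(msg, "base frequencies must be positive and sum to 1")
    if (object@pInvariant < 0 || object@pInvariant >= 1)
      msg <- c(msg, "pInvariant must lie in [0, 1)")
    if (length(msg)) msg else TRUE
  })

#' @describeIn PhyloModel-class constructor. Defaults give Jukes-Cantor
#'   exchangeabilities with the gamma shape used for cervid mitogenome
#'   analyses (alpha = 0.3366, 5 categories).
#' @param rates,baseFreqs,gammaShape,nCategories,pInvariant see slots.
#' @export
PhyloModel <- function(rates = c(AC = 1, AG = 1, AT = 1, CG = 1, CT = 1,
                                 GT = 1),
                       baseFreqs = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                       gammaShape = 0.3366, nCategories = 5,
                       pInvariant = 0) {
  new("PhyloModel", rates = rates, baseFreqs = baseFreqs,
      gammaShape = gammaShape, nCategories = nCategories,
      pInvariant = pInvariant)
}

setMethod("show", "PhyloModel", function(object) {
  cat(sprintf("PhyloModel: GTR+G+I, alpha %.4g (%d categories), pInv %.3g\n",
              object@gammaShape, as.integer(object@nCategories),
              object@pInvariant))
})

#' Collagen quality-control parameters
#'
#' Inclusive atomic C/N ratio window for reliable collagen isotope values
#' (default 2.9-3.6).
#'
#' @slot cnMin,cnMax inclusive bounds on the atomic C/N ratio.
#'
#' @exportClass QCParams
setClass("QCParams",
  representation(cnMin = "numeric", cnMax = "numeric"),
  validity = function(object) {
    if (object@cnMin >= object@cnMax) "cnMin must be < cnMax" else TRUE
  })

#' @describeIn QCParams-class constructor.
#' @param cnMin,cnMax see slots.
#' @export
QCParams <- function(cnMin = 2.9, cnMax = 3.6) {
  new("QCParams", cnMin = cnMin, cnMax = cnMax)
}
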