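# Iterative reference-guided assembly in the style of mapping iterative
# assemblers: map merged reads to a (possibly distant) reference with
# damage-tolerant scoring, collapse duplicates, call a coverage-masked
# consensus, and re-map to successive consensus sequences until the
# consensus stops changing.

#' Map reads to a reference with damage-aware scoring
#'
#' K-mer seeded, banded affine alignment against the (doubled, for circular
#' molecules) reference. Scoring: match +1, mismatch -1, gap open -2, gap
#' extension -1. With `damageAware = TRUE`, C-to-T mismatches near the
#' aligned sequence's 5' end and G-to-A near its 3' end have their penalty
#' multiplied by `1 - damageDecay^p` (p = 1-based distance from the
#' terminus), so terminal deamination artefacts are tolerated while interior
#' mismatches pay full price. Alignments scoring below
#' `minScoreFraction * readLength` are discarded as unmapped.
#'
#' @param seqs character vector of read sequences.
#' @param ref a [ReferenceGenome-class] (or character/DNAString).
#' @param quals optional Phred+33 quality strings.
#' @param ids optional read identifiers.
#' @param damageAware logical; enable terminal damage tolerance.
#' @param damageDecay decay of the terminal mismatch discount (default 0.5).
#' @param minScoreFraction unmapped threshold as a fraction of read length.
#' @param k seed k-mer size.
#' @param band alignment band half-width.
#' @return data.frame of alignment records (`readId`, `start`, `end`
#'   0-based half-open with `end` beyond the reference length for
#'   origin-wrapping alignments, `strand`, `score`, `cigar`, `seq`, `qual`;
#'   `seq`/`qual` are oriented to the reference forward strand). The number
#'   of input reads is kept in `attr(, "totalReads")`.
#' @export
mapReads <- function(seqs, ref, quals = NULL, ids = NULL,
                     damageAware = TRUE, damageDecay = 0.5,
                     minScoreFraction = 0.5, k = 12, band = 8) {
  refseq <- if (is(ref, "ReferenceGenome")) as.character(ref@sequence)
            else as.character(ref)
  circular <- if (is(ref, "ReferenceGenome")) ref@circular else TRUE
  if (nchar(refseq) == 0) stop("empty reference")
  if (is.null(quals)) quals <- strrep(phred_char(37), nchar(seqs))
  if (is.null(ids)) ids <- sprintf("read_%06d", seq_along(seqs))
  res <- cpp_map_reads(seqs, quals, refseq, circular, damageAware,
                       damageDecay, 1.0, -1.0, -2.0, -1.0,
                       minScoreFraction, as.integer(k), as.integer(band),
                       4L)
  keep <- which(res$mapped)
  aln <- data.frame(readId = ids[keep],
                    start = res$start[keep], end = res$end[keep],
                    strand = as.character(res$strand)[keep],
                    score = res$score[keep],
                    cigar = as.character(res$cigar)[keep],
                    seq = as.character(res$seq)[keep],
                    qual = as.character(res$qual)[keep])
  attr(aln, "totalReads") <- length(seqs)
  aln
}

#' Collapse duplicate alignments
#'
#' Alignments sharing identical start, end and strand are taken to be PCR
#' duplicates of the same original molecule; the representative with the
#' highest summed base quality is kept.
#'
#' @param aln alignment data.frame from [mapReads()].
#' @return the unique alignments, one row per distinct coordinate triple.
#' @export
removeDuplicates <- function(aln) {
  if (!nrow(aln)) return(aln)
  qs <- qual_sum(aln$qual)
  key <- paste(aln$start, aln$end, aln$strand)
  ord <- order(key, -qs)
  aln <- aln[ord, , drop = FALSE]
  out <- aln[!duplicated(key[ord]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call a coverage-masked consensus from unique alignments
#'
#' Per-position pileup over the unique reads; the majority base is emitted
#' where coverage reaches `params@minCoverage` and the majority fraction is
#' met, otherwise N. Ties are called N.
#'
#' @param aln duplicate-free alignment data.frame.
#' @param refLength reference length in bp.
#' @param params a [ConsensusParams-class].
#' @param circular logical.
#' @return list with `consensus` ([Biostrings::DNAString]) and `coverage`
#'   (integer depth per position).
#' @export
callConsensus <- function(aln, refLength, params = ConsensusParams(),
                          circular = TRUE) {
  counts <- cpp_pileup(aln$start, aln$cigar, aln$seq,
                       as.integer(refLength), circular)
  cov <- colSums(counts)
  top <- apply(counts, 2, max)
  winner <- apply(counts, 2, which.max)
  ties <- colSums(counts == rep(top, each = 4)) > 1 & top > 0
  frac_ok <- top >= params@majorityFraction * pmax(cov, 1)
  call <- c("A", "C", "G", "T")[winner]
  call[cov < params@minCoverage | ties | !frac_ok] <- "N"
  list(consensus = Biostrings::DNAString(paste(call, collapse = "")),
       coverage = as.integer(cov))
}

#' Iterative reference-guided assembly
#'
#' Repeats map -> duplicate removal -> consensus, substituting the previous
#' round's reference base at N positions for mapping purposes only, until
#' the consensus is identical between rounds or `params@maxIterations` is
#' reached. The final consensus keeps N at positions below the coverage
#' threshold.
#'
#' @param seqs merged-read sequences.
#' @param initialRef a [ReferenceGenome-class]: the (possibly distant)
#'   starting reference.
#' @param quals,ids optional qualities and identifiers.
#' @param params a [ConsensusParams-class].
#' @param damageAware passed to [mapReads()].
#' @param ... further arguments to [mapReads()].
#' @return an [AssemblyResult-class]; `failed` is TRUE when no reads mapped
#'   in the first round.
#' @export
iterateAssembly <- function(seqs, initialRef, quals = NULL, ids = NULL,
                            params = ConsensusParams(), damageAware = TRUE,
                            ...) {
  L <- length(initialRef@sequence)
  mapref <- as.character(initialRef@sequence)
  circular <- initialRef@circular
  prev_consensus <- NULL
  aln <- NULL
  cons <- NULL
  iters <- 0L
  for (it in seq_len(max(1L, as.integer(params@maxIterations)))) {
    refobj <- ReferenceGenome("iter_ref", mapref, circular = circular)
    aln <- mapReads(seqs, refobj, quals = quals, ids = ids,
                    damageAware = damageAware, ...)
    if (it == 1L && nrow(aln) == 0L) {
      return(new("AssemblyResult",
                 consensus = Biostrings::DNAString(strrep("N", L)),
                 coverage = integer(L), uniqueFragments = 0L,
                 iterations = 0L, fractionCovered = 0,
                 alignments = aln, failed = TRUE))
    }
    aln <- removeDuplicates(aln)
    cons <- callConsensus(aln, L, params, circular = circular)
    iters <- it
    cc <- as.character(cons$consensus)
    if (!is.null(prev_consensus) && cc == prev_consensus) break
    prev_consensus <- cc
    # next mapping reference: consensus with N filled from previous reference
    v <- strsplit(cc, "")[[1]]
    w <- strsplit(mapref, "")[[1]]
    v[v == "N"] <- w[v == "N"]
    mapref <- paste(v, collapse = "")
  }
  new("AssemblyResult", consensus = cons$consensus,
      coverage = cons$coverage, uniqueFragments = nrow(aln),
      iterations = iters,
      fractionCovered = mean(cons$coverage >= params@minCoverage),
      alignments = aln, failed = FALSE)
}

#' Assembly summary statistics
#'
#' The standard reporting columns for an ancient mtDNA assembly: total
#' merged reads, unique mapped reads, unique average coverage, average read
#' length, and fraction of the reference covered at the calling threshold.
#'
#' @param result an [AssemblyResult-class].
#' @param totalMergedReads number of merged reads given to the assembler.
#' @return one-row data.frame.
#' @export
assemblyStats <- function(result, totalMergedReads = NA_integer_) {
  data.frame(
    total_merged_reads = totalMergedReads,
    unique_mapped_reads = result@uniqueFragments,
    unique_average_coverage = mean(result@coverage),
    average_read_length = if (nrow(result@alignments))
      mean(nchar(result@alignments$seq)) else NA_real_,
    consensus_completeness = result@fractionCovered)
}
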