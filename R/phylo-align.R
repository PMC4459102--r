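# Alignment masking (region exclusion, gap/missing-column elimination,
# coverage masks for ancient taxa) and pairwise mismatch counting for
# protein-coding regions such as cytochrome b.

#' Mask alignment columns
#'
#' Removes columns that fall in excluded regions (e.g. the hypervariable
#' D-loop), columns containing any gap or missing/ambiguous character
#' (complete deletion), and columns where any listed ancient taxon has
#' coverage below `minCoverage`.
#'
#' @param aln character matrix (taxa x sites).
#' @param excludeRegions optional data.frame with `start`, `end` (0-based
#'   half-open alignment coordinates).
#' @param coverageMasks optional named list (one element per ancient taxon)
#'   of integer coverage vectors along alignment columns.
#' @param minCoverage minimum coverage for ancient taxa (default 3).
#' @return list with `alignment` (retained columns), `retainedColumns`
#'   (1-based indices), `nRetained` and `mask` (logical keep per column).
#' @export
maskAlignment <- function(aln, excludeRegions = NULL, coverageMasks = NULL,
                          minCoverage = 3) {
  aln <- as_alignment(aln)
  nc <- ncol(aln)
  keep <- rep(TRUE, nc)
  if (!is.null(excludeRegions) && nrow(excludeRegions)) {
    if (any(excludeRegions$start < 0) || any(excludeRegions$end > nc) ||
        any(excludeRegions$end <= excludeRegions$start))
      stop("exclusion interval out of alignment range")
    for (i in seq_len(nrow(excludeRegions)))
      keep[(excludeRegions$start[i] + 1):excludeRegions$end[i]] <- FALSE
  }
  keep <- keep & apply(aln, 2, function(col) all(col %in% BASES))
  if (!is.null(coverageMasks)) {
    for (cv in coverageMasks) {
      if (length(cv) != nc)
        stop("coverage mask length must match the alignment")
      keep <- keep & cv >= minCoverage
    }
  }
  list(alignment = aln[, keep, drop = FALSE],
       retainedColumns = which(keep), nRetained = sum(keep), mask = keep)
}

#' Count pairwise nucleotide mismatches over aligned sequences
#'
#' Mismatches are counted only at columns where both bases are unambiguous
#' A/C/G/T; columns containing N, gaps or other ambiguity codes are
#' reported as unresolved rather than as differences.
#'
#' @param seqA,seqB aligned sequences of equal length (character strings or
#'   character vectors).
#' @return named numeric: `mismatches`, `comparedSites`, `unresolvedSites`.
#' @examples
#' countMismatches("ACGTN", "ACTTA")  # 1 mismatch, 4 compared, 1 unresolved
#' @export
countMismatches <- function(seqA, seqB) {
  a <- if (length(seqA) == 1) strsplit(toupper(seqA), "")[[1]] else toupper(seqA)
  b <- if (length(seqB) == 1) strsplit(toupper(seqB), "")[[1]] else toupper(seqB)
  if (length(a) != length(b))
    stop("aligned sequences must have equal length")
  both <- a %in% BASES & b %in% BASES
  c(mismatches = sum(a[both] != b[both]),
    comparedSites = sum(both),
    unresolvedSites = length(a) - sum(both))
}

#' Extract an annotated region from a sequence by pairwise alignment
#'
#' Locates a reference-annotated region (e.g. cytb) inside a reconstructed
#' sequence by global-local pairwise alignment of the annotated region
#' against the query, rather than by fixed coordinates.
#'
#' @param query the reconstructed sequence (character or DNAString; may
#'   contain N).
#' @param ref a [ReferenceGenome-class] with the region annotated.
#' @param region annotation name (e.g. `"cytb"`).
#' @return list with aligned `ref` and `query` strings (equal length),
#'   ready for [countMismatches()].
#' @export
extractRegionByAlignment <- function(query, ref, region) {
  a <- ref@annotations
  row <- a[a$name == region, ]
  if (!nrow(row)) stop("region '", region, "' not annotated")
  regionSeq <- decodeFragment(ref, row$start[1], row$end[1])
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(regionSeq),
    subject = Biostrings::DNAString(as.character(query)),
    type = "global-local")
  list(ref = as.character(Biostrings::alignedPattern(pa)),
       query = as.character(Biostrings::alignedSubject(pa)))
}

#' Pairwise mismatch matrix between query and reference sequences
#'
#' Globally aligns every query against every reference sequence and counts
#' mismatches, compared and unresolved sites — the layout used for
#' cytochrome-b comparisons of reconstructed ancient sequences against
#' published references.
#'
#' @param queries named character vector of query sequences.
#' @param refs named character vector of reference sequences.
#' @return data.frame with one row per (query, ref) pair.
#' @export
pairwiseMismatchMatrix <- function(queries, refs) {
  out <- expand.grid(query = names(queries), ref = names(refs),
                     stringsAsFactors = FALSE)
  res <- t(vapply(seq_len(nrow(out)), function(i) {
    pa <- Biostrings::pairwiseAlignment(
      pattern = Biostrings::DNAString(queries[[out$query[i]]]),
      subject = Biostrings::DNAString(refs[[out$ref[i]]]),
      type = "global")
    countMismatches(as.character(Biostrings::alignedPattern(pa)),
                    as.character(Biostrings::alignedSubject(pa)))
  }, numeric(3)))
  cbind(out, as.data.frame(res))
}
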