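# Paired-read merging and length filtering. Forward and reverse reads are
# merged into single sequences when they overlap by at least minOverlap bp
# (default 11); unmerged pairs are discarded and merged reads are filtered
# for a minimum length (default 30 bp). Adapter read-through is removed
# implicitly by the merge geometry.

#' Merge paired reads by overlap
#'
#' Scans all relative placements of mate 1 against the reverse complement of
#' mate 2 and accepts the best-scoring overlap of at least
#' `params@minOverlap` bases whose mismatch fraction does not exceed
#' `params@maxMismatchFraction` (N bases count as mismatches). In the
#' overlap the base with the higher quality wins and its quality is kept
#' (ties favour mate 1). Pairs without an acceptable overlap are reported
#' as `"unmerged"`.
#'
#' @param seq1,seq2 character vectors of mate sequences.
#' @param qual1,qual2 Phred+33 quality strings (defaults: constant Q37).
#' @param ids read identifiers.
#' @param params a [MergeParams-class].
#' @return data.frame with columns `id`, `seq`, `qual`, `overlap`, `status`
#'   (`"merged"`/`"unmerged"`; `seq` is NA for unmerged pairs).
#' @examples
#' frag <- "ACGTACGGTTACGATACGGATTACA"
#' m <- mergePairs(substr(frag, 1, 18),
#'                 as.character(Biostrings::reverseComplement(
#'                   Biostrings::DNAString(substr(frag, 8, 25)))))
#' m$overlap  # 11
#' @export
mergePairs <- function(seq1, seq2, qual1 = NULL, qual2 = NULL, ids = NULL,
                       params = MergeParams()) {
  if (length(seq1) != length(seq2)) stop("mates must pair up")
  if (any(nchar(seq1) == 0L) || any(nchar(seq2) == 0L))
    stop("malformed pair: empty mate sequence")
  if (is.null(qual1)) qual1 <- strrep(phred_char(37), nchar(seq1))
  if (is.null(qual2)) qual2 <- strrep(phred_char(37), nchar(seq2))
  if (any(nchar(seq1) != nchar(qual1)) || any(nchar(seq2) != nchar(qual2)))
    stop("malformed pair: sequence/quality length mismatch")
  if (is.null(ids)) ids <- sprintf("pair_%06d", seq_along(seq1))
  out <- cpp_merge_pairs(seq1, qual1, seq2, qual2,
                         as.integer(params@minOverlap),
                         params@maxMismatchFraction)
  data.frame(id = ids, seq = as.character(out$seq),
             qual = as.character(out$qual),
             overlap = out$overlap, status = as.character(out$status))
}

#' Length-filter merged reads
#'
#' Retains merged reads of length at least `params@minLength`; unmerged
#' pairs and short merged reads are logged by discard reason.
#'
#' @param merged data.frame as returned by [mergePairs()].
#' @param params a [MergeParams-class].
#' @return list with `retained` (data.frame of surviving merged reads) and
#'   `log` (named counts: `total`, `merged`, `discarded_unmerged`,
#'   `discarded_short`, `retained`).
#' @export
filterMerged <- function(merged, params = MergeParams()) {
  unm <- merged$status != "merged"
  short <- !unm & nchar(merged$seq) < params@minLength
  keep <- !unm & !short
  list(retained = merged[keep, , drop = FALSE],
       log = c(total = nrow(merged), merged = sum(!unm),
               discarded_unmerged = sum(unm),
               discarded_short = sum(short), retained = sum(keep)))
}

#' Merge two FASTQ files
#'
#' File-level wrapper over [mergePairs()] and [filterMerged()]: reads two
#' FASTQ files, writes the retained merged reads as FASTQ and the merge
#' statistics as a TSV.
#'
#' @param r1,r2 input FASTQ paths (mates in matching order).
#' @param out output FASTQ path for retained merged reads.
#' @param statsOut optional TSV path for merge statistics.
#' @param params a [MergeParams-class].
#' @return invisibly, the `filterMerged()` result.
#' @export
mergeFastq <- function(r1, r2, out, statsOut = NULL,
                       params = MergeParams()) {
  f1 <- readFastq(r1); f2 <- readFastq(r2)
  m <- mergePairs(f1$seq, f2$seq, f1$qual, f2$qual, ids = f1$id,
                  params = params)
  res <- filterMerged(m, params)
  write_fastq(res$retained$id, res$retained$seq, res$retained$qual, out)
  if (!is.null(statsOut)) {
    df <- data.frame(metric = names(res$log), value = as.integer(res$log))
    write.table(df, statsOut, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(res)
}
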