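# Terminal misincorporation profiling and the ancient-DNA authenticity
# rule: libraries whose 5'-terminal C-to-T and 3'-terminal G-to-A
# frequencies both reach 20% are regarded as authentic ancient DNA.

BASES <- c("A", "C", "G", "T")

#' Profile terminal misincorporation frequencies
#'
#' Counts all twelve substitution types at the first `K` positions from the
#' read 5' and 3' ends (read orientation; minus-strand alignments are
#' complemented), conditioning each frequency on the number of aligned
#' reference-base opportunities: frequency(X>Y at p) = count(X>Y at p) /
#' count(ref = X at p). Consensus N positions are excluded from
#' opportunities; positions with zero opportunities report NA.
#'
#' @param aln alignment data.frame from [mapReads()] (against the final
#'   consensus or reference).
#' @param consensus the sequence the reads are aligned to
#'   ([Biostrings::DNAString] or character; may contain N).
#' @param K number of terminal positions to profile (default 25).
#' @param circular logical.
#' @return a [MisincorporationTable-class].
#' @export
profileDamage <- function(aln, consensus, K = 25, circular = TRUE) {
  cons <- as.character(consensus)
  res <- cpp_damage_counts(aln$start, aln$cigar, aln$seq, aln$strand,
                           cons, as.integer(K), circular)
  build <- function(counts, end) {
    a <- array(counts, dim = c(4, 4, K))  # read, ref, position
    do.call(rbind, lapply(seq_len(K), function(p) {
      m <- t(a[, , p])                    # ref x read
      opp <- rowSums(m)
      do.call(rbind, lapply(1:4, function(x) {
        ys <- setdiff(1:4, x)
        data.frame(end = end, position = p,
                   sub = paste0(BASES[x], ">", BASES[ys]),
                   count = m[x, ys],
                   opportunities = opp[x],
                   frequency = if (opp[x] > 0) m[x, ys] / opp[x]
                               else rep(NA_real_, length(ys)))
      }))
    }))
  }
  tab <- rbind(build(res$five, "5p"), build(res$three, "3p"))
  rownames(tab) <- NULL
  new("MisincorporationTable", table = tab, K = as.integer(K))
}

#' Extract a substitution frequency from a misincorporation table
#'
#' @param x a [MisincorporationTable-class].
#' @param end `"5p"` or `"3p"`.
#' @param sub substitution label such as `"C>T"`.
#' @param position 1-based terminal position (default 1).
#' @return the conditional frequency (NA when undefined).
#' @export
terminalFrequency <- function(x, end, sub, position = 1) {
  tab <- x@table
  row <- tab[tab$end == end & tab$sub == sub & tab$position == position, ]
  if (!nrow(row)) NA_real_ else row$frequency
}

#' Apply the terminal-damage authenticity rule
#'
#' A library is called authentic ancient DNA when both the 5'-terminal
#' C-to-T and the 3'-terminal G-to-A frequency are at least `threshold`
#' (default 20%). When either terminal frequency is undefined the verdict
#' is indeterminate (NA).
#'
#' @param x a [MisincorporationTable-class].
#' @param threshold authentication threshold (default 0.20).
#' @return an [AuthenticationVerdict-class].
#' @examples
#' # frequencies of 27% and 25% pass the 20% rule
#' @export
authenticate <- function(x, threshold = 0.20) {
  ct <- terminalFrequency(x, "5p", "C>T")
  ga <- terminalFrequency(x, "3p", "G>A")
  verdict <- if (is.na(ct) || is.na(ga)) NA else
    ct >= threshold && ga >= threshold
  new("AuthenticationVerdict", c2t5prime = ct, g2a3prime = ga,
      threshold = threshold, authentic = verdict)
}

#' Write a misincorporation table as TSV
#'
#' @param x a [MisincorporationTable-class].
#' @param path output TSV path.
#' @export
writeMisincorporation <- function(x, path) {
  write.table(x@table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
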