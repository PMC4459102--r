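# Simulation of every input the pipeline consumes: circular references,
# ancient fragment sets with overhang-restricted deamination, paired FASTQ
# emission with adapter read-through, and collagen isotope tables.
# Alignment simulation on trees lives in phylo-model.R.

#' Simulate a circular reference genome
#'
#' Draws an i.i.d. nucleotide sequence with the requested GC fraction
#' (G and C equiprobable, likewise A and T).
#'
#' @param length genome length in bp (>= 100).
#' @param gc GC fraction in `[0, 1)`; 0 gives an all-A/T sequence.
#' @param seed integer seed; the same seed reproduces the same genome.
#' @param id identifier for the genome.
#' @param circular logical.
#' @param annotations optional data.frame (`name`, `start`, `end`, 0-based
#'   half-open), e.g. D-loop and cytb intervals.
#' @return a [ReferenceGenome-class].
#' @examples
#' ref <- simulateReference(16500, gc = 0.4, seed = 1)
#' @export
simulateReference <- function(length, gc, seed, id = "sim_ref",
                              circular = TRUE, annotations = NULL) {
  stopifnot_scalar(length, "length"); stopifnot_scalar(gc, "gc")
  if (length < 100) stop("length must be >= 100")
  if (gc < 0 || gc >= 1) stop("gc must lie in [0, 1)")
  seq <- with_seed(seed, {
    probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    paste(sample(names(probs), length, replace = TRUE, prob = probs),
          collapse = "")
  })
  if (is.null(annotations))
    annotations <- data.frame(name = character(), start = integer(),
                              end = integer())
  ReferenceGenome(id = id, sequence = seq, circular = circular,
                  annotations = annotations)
}

#' Simulate fragment coordinates from a reference
#'
#' Draws uniformly placed fragments until the total fragment length reaches
#' approximately `coverageTarget` times the genome length. Lengths follow
#' `minLength` + NB(size = `dispersion`, mu = `meanLength - minLength`).
#' On circular references fragments may wrap the origin (`end` then exceeds
#' the genome length).
#'
#' @param ref a [ReferenceGenome-class].
#' @param frag a [FragmentationModel-class].
#' @param seed integer seed.
#' @param n optional explicit fragment count overriding the coverage target.
#' @return data.frame with columns `start`, `end` (0-based half-open),
#'   `strand`, `length`.
#' @export
simulateFragments <- function(ref, frag, seed, n = NULL) {
  L <- length(ref@sequence)
  if (is.null(n)) {
    if (frag@coverageTarget <= 0) stop("coverageTarget must be > 0")
    n <- max(1L, round(frag@coverageTarget * L / frag@meanLength))
  }
  with_seed(seed, {
    len <- frag@minLength +
      rnbinom(n, size = frag@dispersion,
              mu = max(frag@meanLength - frag@minLength, 1e-9))
    len <- pmin(len, L)
    start <- sample.int(L, n, replace = TRUE) - 1L
    if (!ref@circular) start <- pmin(start, L - len)
    strand <- sample(c("+", "-"), n, replace = TRUE)
    data.frame(start = as.integer(start),
               end = as.integer(start + len),
               strand = strand, length = as.integer(len))
  })
}

#' Apply post-mortem deamination to fragment sequences
#'
#' Sequences are taken in read orientation. Under the double-strand protocol
#' each fragment is, with probability 1/2, read in the sense of its
#' deaminated template strand (C-to-T accumulating from the 5' end) and
#' otherwise in the complementary sense (the same lesions appearing as
#' G-to-A from the 3' end). Under the single-strand protocol every read is
#' template-sense with single-stranded overhangs at both ends.
#'
#' @param seqs character vector of fragment sequences (read orientation).
#' @param model a [DamageModel-class].
#' @param seed integer seed.
#' @return list with `seq` (damaged sequences), `positions` (list of 1-based
#'   altered positions per fragment, the simulation ground truth) and
#'   `sense` (0 template, 1 complement, 2 single-strand).
#' @export
applyDamage <- function(seqs, model, seed) {
  if (any(nchar(seqs) == 0)) stop("fragments must be non-empty")
  with_seed(seed, {
    sense <- if (model@bothStrands)
      sample(c(0L, 1L), length(seqs), replace = TRUE) else
      rep(2L, length(seqs))
    out <- cpp_apply_damage(seqs, sense, model@overhangDecay,
                            model@deltaSS, model@deltaDS)
    list(seq = as.character(out$seq), positions = out$positions,
         sense = sense)
  })
}

#' Emit paired-end FASTQ files from fragment sequences
#'
#' Mate 1 reads the fragment from its 5' end, mate 2 is the reverse
#' complement read from the other end; fragments shorter than `readLength`
#' read through into the adapter (recycled to fill the read). Qualities are
#' constant Q37; sequencing errors are applied uniformly at `errorRate`.
#'
#' @param seqs character vector of fragment sequences (read orientation).
#' @param readLength sequencing read length in bp.
#' @param adapter adapter sequence appended after short fragments.
#' @param errorRate per-base uniform substitution error probability.
#' @param out1,out2 output FASTQ paths.
#' @param seed integer seed (errors).
#' @param ids optional read identifiers.
#' @return invisibly, a list with the mate sequences and ids.
#' @export
emitFastqPairs <- function(seqs, readLength = 100,
                           adapter = "AGATCGGAAGAGCACACGTCTGAACTCCAGTCAC",
                           errorRate = 0, out1, out2, seed = 1,
                           ids = NULL) {
  if (readLength <= 0) stop("readLength must be > 0")
  if (is.null(ids)) ids <- sprintf("read_%06d", seq_along(seqs))
  fill <- function(x) {
    pad <- readLength - nchar(x)
    need <- pmax(pad, 0)
    adp <- strrep(adapter, ceiling(max(need, 1) / nchar(adapter)))
    ifelse(pad > 0, paste0(x, substring(adp, 1, need)),
           substring(x, 1, readLength))
  }
  r1 <- fill(seqs)
  r2 <- fill(reverseComplement_chr(seqs))
  if (errorRate > 0) {
    r1 <- with_seed(derive_seed(seed, 1), add_seq_errors(r1, errorRate))
    r2 <- with_seed(derive_seed(seed, 2), add_seq_errors(r2, errorRate))
  }
  qual <- strrep(phred_char(37), readLength)
  write_fastq(ids, r1, rep(qual, length(r1)), out1)
  write_fastq(ids, r2, rep(qual, length(r2)), out2)
  invisible(list(id = ids, read1 = r1, read2 = r2))
}

add_seq_errors <- function(seqs, rate) {
  vapply(seqs, function(s) {
    n <- nchar(s)
    hit <- which(runif(n) < rate)
    if (!length(hit)) return(s)
    v <- strsplit(s, "")[[1]]
    for (i in hit) {
      alt <- setdiff(c("A", "C", "G", "T"), v[i])
      v[i] <- alt[sample.int(length(alt), 1)]
    }
    paste(v, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

write_fastq <- function(ids, seqs, quals, path) {
  x <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(setNames(seqs, ids)),
    Biostrings::PhredQuality(quals))
  Biostrings::writeQualityScaledXStringSet(x, path)
  invisible(path)
}

#' Read a FASTQ file into sequences and qualities
#'
#' @param path FASTQ file path.
#' @return data.frame with `id`, `seq`, `qual`.
#' @export
readFastq <- function(path) {
  # the FASTQ reader attaches quality metadata that the quality-scaled
  # container re-derives; dropping it is expected, not noteworthy
  x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  data.frame(id = names(x), seq = as.character(x),
             qual = as.character(Biostrings::quality(x)),
             row.names = NULL)
}

#' Simulate a full ancient read set
#'
#' Convenience wrapper: draws fragments, extracts read-oriented sequences,
#' applies deamination, and (optionally) emits paired FASTQ files. The
#' returned ground truth records fragment coordinates, strands, damage
#' positions and the damage sense of every read.
#'
#' @param ref a [ReferenceGenome-class].
#' @param frag a [FragmentationModel-class].
#' @param damage a [DamageModel-class] or NULL for an undamaged
#'   (contaminant/blank-like) library.
#' @param seed integer seed.
#' @param n optional explicit fragment count.
#' @return list with `fragments` (coordinates + truth), `seq` (damaged
#'   read-oriented sequences) and `damagePositions`.
#' @export
simulateReadSet <- function(ref, frag, damage = NULL, seed = 1, n = NULL) {
  fr <- simulateFragments(ref, frag, derive_seed(seed, 11), n = n)
  raw <- vapply(seq_len(nrow(fr)), function(i)
    decodeFragment(ref, fr$start[i], fr$end[i]), character(1))
  minus <- fr$strand == "-"
  raw[minus] <- reverseComplement_chr(raw[minus])
  if (is.null(damage)) {
    return(list(fragments = fr, seq = raw,
                damagePositions = rep(list(integer()), nrow(fr))))
  }
  dmg <- applyDamage(raw, damage, derive_seed(seed, 12))
  fr$sense <- dmg$sense
  list(fragments = fr, seq = dmg$seq, damagePositions = dmg$positions)
}

#' Simulate a collagen stable-isotope table
#'
#' Per-group normal draws of d13C/d15N with added analytic noise (defaults
#' 0.1 permil for d13C, 0.2 permil for d15N), plus elemental composition
#' columns. A configurable fraction of records receives an atomic C/N ratio
#' outside the 2.9-3.6 reliability window to exercise quality control.
#'
#' @param groups data.frame with columns `taxon`, `period`, `meanD13C`,
#'   `meanD15N`, `sdD13C`, `sdD15N`, `n`.
#' @param seed integer seed.
#' @param analyticNoise numeric(2): measurement sds for d13C and d15N.
#' @param invalidFraction fraction of records given C/N outside the window.
#' @return data.frame with columns `sample`, `taxon`, `period`, `d13C`,
#'   `d15N`, `pctC`, `pctN`.
#' @export
simulateIsotopeTable <- function(groups, seed,
                                 analyticNoise = c(0.1, 0.2),
                                 invalidFraction = 0) {
  if (!nrow(groups)) stop("groups must be non-empty")
  if (any(groups$n < 1)) stop("each group needs n >= 1")
  if (any(groups$sdD13C < 0 | groups$sdD15N < 0)) stop("sds must be >= 0")
  with_seed(seed, {
    rows <- do.call(rbind, lapply(seq_len(nrow(groups)), function(i) {
      g <- groups[i, ]
      data.frame(
        taxon = g$taxon, period = g$period,
        d13C = rnorm(g$n, g$meanD13C, g$sdD13C) +
          rnorm(g$n, 0, analyticNoise[1]),
        d15N = rnorm(g$n, g$meanD15N, g$sdD15N) +
          rnorm(g$n, 0, analyticNoise[2]))
    }))
    n <- nrow(rows)
    bad <- runif(n) < invalidFraction
    cn <- ifelse(bad,
                 ifelse(runif(n) < 0.5, runif(n, 2.2, 2.85),
                        runif(n, 3.65, 4.5)),
                 runif(n, 2.95, 3.55))
    pctN <- rnorm(n, 15.5, 0.8)
    pctC <- cn * pctN * 12.011 / 14.007
    data.frame(sample = sprintf("S%04d", seq_len(n)),
               taxon = rows$taxon, period = rows$period,
               d13C = rows$d13C, d15N = rows$d15N,
               pctC = pctC, pctN = pctN)
  })
}
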