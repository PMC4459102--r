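# Shared fixtures and independent oracles used across the suite.

random_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))

# Construct a mate pair from a fragment: read 1 from the 5' end, read 2
# reverse-complemented from the 3' end, with adapter read-through.
pair_from_fragment <- function(frag, readLength,
                               adapter = "AGATCGGAAGAGCACACGTCTGAACTCCAGTCAC") {
  fill <- function(x) {
    if (nchar(x) >= readLength) return(substr(x, 1, readLength))
    adp <- strrep(adapter, ceiling(readLength / nchar(adapter)))
    paste0(x, substr(adp, 1, readLength - nchar(x)))
  }
  list(r1 = fill(frag), r2 = fill(revcomp(frag)))
}

# Brute-force merge oracle: independent R re-implementation scanning every
# candidate fragment length, same scoring and tie-break contract.
merge_oracle <- function(s1, s2, min_overlap = 11, max_mm = 0.1) {
  rc2 <- revcomp(s2)
  l1 <- nchar(s1); l2 <- nchar(s2)
  v1 <- strsplit(s1, "")[[1]]; v2 <- strsplit(rc2, "")[[1]]
  best <- NULL
  for (f in seq_len(l1 + l2 - min_overlap)) {
    lo <- max(0, f - l2); hi <- min(l1, f)
    ov <- hi - lo
    if (ov < min_overlap) next
    i1 <- (lo + 1):hi
    i2 <- i1 - (f - l2)
    match <- sum(v1[i1] == v2[i2] & v1[i1] %in% c("A", "C", "G", "T"))
    mm <- ov - match
    score <- match - mm
    cand <- list(f = f, ov = ov, mm = mm, score = score)
    if (is.null(best) || score > best$score ||
        (score == best$score && (ov > best$ov ||
                                 (ov == best$ov && f < best$f))))
      best <- cand
  }
  if (is.null(best) || best$score <= 0 || best$mm / best$ov > max_mm)
    return(NULL)
  merged <- character(best$f)
  for (x in seq_len(best$f)) {
    merged[x] <- if (x <= l1) v1[x] else v2[x - (best$f - l2)]
  }
  list(seq = paste(merged, collapse = ""), overlap = best$ov, f = best$f)
}

# Exhaustive ungapped mapping oracle: best scoring offset/strand over the
# doubled reference, match +1 / mismatch -1, no damage discount.
map_oracle <- function(read, refseq, circular = TRUE) {
  ext <- if (circular) paste0(refseq, refseq) else refseq
  m <- nchar(read)
  ev <- strsplit(ext, "")[[1]]
  best <- list(score = -Inf)
  for (strand in c("+", "-")) {
    s <- if (strand == "+") read else revcomp(read)
    sv <- strsplit(s, "")[[1]]
    for (start in 0:(nchar(ext) - m)) {
      sc <- sum(sv == ev[(start + 1):(start + m)]) * 2 - m
      if (sc > best$score) {
        st <- start %% nchar(refseq)
        best <- list(score = sc, start = st, strand = strand)
      }
    }
  }
  best
}

# Brute-force parsimony: minimum substitutions over all internal-state
# assignments, per site.
parsimony_oracle <- function(aln, tree) {
  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tr$tip.label)
  internal <- unique(as.vector(tr$edge[tr$edge > ntip]))
  total <- 0
  for (j in seq_len(ncol(aln))) {
    tipstate <- match(aln[tr$tip.label, j], c("A", "C", "G", "T"))
    grid <- as.matrix(expand.grid(rep(list(1:4), length(internal))))
    best <- Inf
    for (g in seq_len(nrow(grid))) {
      st <- integer(ntip + tr$Nnode)
      st[seq_len(ntip)] <- tipstate
      st[internal] <- grid[g, ]
      cost <- sum(st[tr$edge[, 1]] != st[tr$edge[, 2]])
      if (anyNA(tipstate)) cost <- NA  # only unambiguous sites here
      best <- min(best, cost)
    }
    total <- total + best
  }
  total
}

# Brute-force pruning oracle: site likelihood by summing over all internal
# node states (no rate variation handled here; category rate passed in).
loglik_oracle <- function(aln, tree, model) {
  Q <- gtrRateMatrix(model)
  pi <- model@baseFreqs
  rates <- ancientMito:::modelRates(model)
  pInv <- model@pInvariant
  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tr$tip.label)
  root <- tr$edge[nrow(tr$edge), 1]
  internal <- unique(as.vector(tr$edge[tr$edge > ntip]))
  total <- 0
  for (j in seq_len(ncol(aln))) {
    tipstate <- match(aln[tr$tip.label, j], c("A", "C", "G", "T"))
    varlik <- 0
    for (r in rates) {
      P <- lapply(tr$edge.length, function(t)
        as.matrix(Matrix::expm(Q * t * r)))
      grid <- as.matrix(expand.grid(rep(list(1:4), length(internal))))
      sl <- 0
      for (g in seq_len(nrow(grid))) {
        st <- integer(ntip + tr$Nnode)
        st[seq_len(ntip)] <- tipstate
        st[internal] <- grid[g, ]
        p <- pi[st[root]]
        for (k in seq_len(nrow(tr$edge)))
          p <- p * P[[k]][st[tr$edge[k, 1]], st[tr$edge[k, 2]]]
        sl <- sl + p
      }
      varlik <- varlik + sl / length(rates)
    }
    u <- unique(aln[, j])
    invlik <- if (length(u) == 1) pi[u] else 0
    total <- total + log(pInv * invlik + (1 - pInv) * varlik)
  }
  as.numeric(total)
}

# Ground-truth alignment records from a simulated read set (bypasses the
# mapper; coordinates and strands from the simulator).
truth_alignments <- function(sim, L = NULL) {
  fr <- sim$fragments
  seq_ref <- ifelse(fr$strand == "-", revcomp(sim$seq), sim$seq)
  data.frame(readId = sprintf("read_%06d", seq_len(nrow(fr))),
             start = fr$start, end = fr$end, strand = fr$strand,
             score = fr$length, cigar = paste0(fr$length, "M"),
             seq = seq_ref, qual = strrep("F", nchar(sim$seq)))
}

# Reference with isolated, evenly spread SNPs at the requested rate.
diverged_reference <- function(truth, rate, seed) {
  tv <- strsplit(as.character(truth@sequence), "")[[1]]
  pos <- round(seq(7, length(tv) - 3, by = 1 / rate))
  set.seed(seed)
  for (i in pos) tv[i] <- sample(setdiff(c("A", "C", "G", "T"), tv[i]), 1)
  ReferenceGenome("diverged", paste(tv, collapse = ""),
                  circular = truth@circular)
}
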