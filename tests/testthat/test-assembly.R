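test_that("exact substrings map at the true locus with an all-match CIGAR", {
  ref <- simulateReference(2000, 0.4, seed = 41)
  rs <- as.character(ref@sequence)
  read <- substr(rs, 501, 540)
  aln <- mapReads(read, ref)
  expect_equal(nrow(aln), 1)
  expect_equal(aln$start, 500)
  expect_equal(aln$end, 540)
  expect_identical(aln$strand, "+")
  expect_identical(aln$cigar, "40M")
  expect_equal(aln$score, 40)

  # reverse-complemented read maps to the same locus on the minus strand
  alnm <- mapReads(revcomp(read), ref)
  expect_equal(alnm$start, 500)
  expect_identical(alnm$strand, "-")
})

test_that("reads spanning the circular origin map with wrap-around coordinates", {
  ref <- simulateReference(2000, 0.4, seed = 42)
  read <- decodeFragment(ref, 1980, 2030)
  aln <- mapReads(read, ref)
  expect_equal(aln$start, 1980)
  expect_equal(aln$end, 2030)
  expect_identical(aln$cigar, "50M")
})

test_that("damage-aware scoring discounts terminal deamination mismatches exactly", {
  ref <- simulateReference(2000, 0.4, seed = 43)
  rs <- as.character(ref@sequence)
  # find a 40-mer starting with C and plant a 5'-terminal C->T
  starts <- which(strsplit(rs, "")[[1]] == "C")
  s0 <- starts[starts > 100 & starts < 1500][1]
  read <- substr(rs, s0, s0 + 39)
  damaged <- paste0("T", substr(read, 2, 40))
  aware <- mapReads(damaged, ref, damageAware = TRUE)
  naive <- mapReads(damaged, ref, damageAware = FALSE)
  # 39 matches plus one discounted mismatch: -1 * (1 - 0.5^1) = -0.5
  expect_equal(aware$score, 39 - 0.5)
  expect_equal(naive$score, 39 - 1)
  expect_gt(aware$score, naive$score)
  expect_equal(aware$start, s0 - 1)
})

test_that("the banded mapper recovers the exhaustive best locus on small cases", {
  set.seed(44)
  refseq <- random_seq(200)
  ref <- ReferenceGenome("toy", refseq, circular = TRUE)
  for (case in 1:25) {
    start <- sample(0:190, 1)
    len <- sample(20:30, 1)
    read <- decodeFragment(ref, start, start + len)
    if (case %% 2 == 0) read <- revcomp(read)
    if (case %% 5 == 0) {  # one interior mismatch
      v <- strsplit(read, "")[[1]]
      i <- sample(5:(len - 5), 1)
      v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1)
      read <- paste(v, collapse = "")
    }
    got <- mapReads(read, ref, damageAware = FALSE, k = 10)
    want <- map_oracle(read, refseq)
    expect_equal(got$score, want$score)
    expect_equal(got$start, want$start)
    expect_identical(got$strand, want$strand)
  }
})

test_that("duplicate removal collapses identical coordinate triples", {
  ref <- simulateReference(1000, 0.4, seed = 45)
  rs <- as.character(ref@sequence)
  read <- substr(rs, 101, 160)
  aln <- mapReads(rep(read, 5), ref)
  expect_equal(nrow(aln), 5)
  expect_equal(nrow(removeDuplicates(aln)), 1)

  # distinct end coordinates are kept
  aln2 <- mapReads(c(substr(rs, 101, 160), substr(rs, 101, 161)), ref)
  expect_equal(nrow(removeDuplicates(aln2)), 2)

  # the highest-quality copy survives
  aln3 <- mapReads(rep(read, 3), ref,
                   quals = c(strrep("#", 60), strrep("I", 60),
                             strrep("5", 60)),
                   ids = c("low", "high", "mid"))
  expect_identical(removeDuplicates(aln3)$readId, "high")
})

test_that("duplicate fraction matches the occupancy-model expectation", {
  ref <- simulateReference(2000, 0.4, seed = 46)
  rs <- as.character(ref@sequence)
  # n draws from J equally likely distinct fragments
  J <- 300; n <- 600
  set.seed(47)
  starts <- seq(0, by = 5, length.out = J)
  pick <- sample(J, n, replace = TRUE)
  reads <- substring(rs, starts[pick] + 1, starts[pick] + 40)
  aln <- mapReads(reads, ref)
  uniq <- nrow(removeDuplicates(aln))
  expected <- J * (1 - (1 - 1 / J)^n)
  expect_lt(abs(uniq - expected), 3 * sqrt(J))
})

test_that("consensus calling enforces 3-fold coverage and the tie rule", {
  # hand-built pileups via synthetic alignment records on a 10 bp reference
  mkaln <- function(seqs, start = 0) {
    data.frame(readId = sprintf("r%d", seq_along(seqs)), start = start,
               end = start + nchar(seqs[1]), strand = "+", score = 1,
               cigar = paste0(nchar(seqs[1]), "M"), seq = seqs,
               qual = strrep("F", nchar(seqs)))
  }
  # positions 1-5: {AAAAA x3} -> called; coverage 3
  cons3 <- callConsensus(mkaln(rep("AAAAA", 3)), 10, circular = FALSE)
  expect_identical(substr(as.character(cons3$consensus), 1, 5), "AAAAA")
  expect_identical(substr(as.character(cons3$consensus), 6, 10), "NNNNN")

  cons2 <- callConsensus(mkaln(rep("AAAAA", 2)), 10, circular = FALSE)
  expect_identical(substr(as.character(cons2$consensus), 1, 5), "NNNNN")

  # {A,A,T,T} tie -> N even at 4x coverage
  tie <- callConsensus(mkaln(c("AAAAA", "AAAAA", "TTTTT", "TTTTT")), 10,
                       circular = FALSE)
  expect_identical(substr(as.character(tie$consensus), 1, 5), "NNNNN")

  # {A,A,A,T} majority -> A
  maj <- callConsensus(mkaln(c("AAAAA", "AAAAA", "AAAAA", "TTTTT")), 10,
                       circular = FALSE)
  expect_identical(substr(as.character(maj$consensus), 1, 5), "AAAAA")
})

test_that("error-free tiling reads reconstruct a toy reference exactly", {
  ref <- simulateReference(100, 0.5, seed = 48, circular = FALSE)
  rs <- as.character(ref@sequence)
  starts <- seq(0, 70, by = 7)
  reads <- substring(rs, starts + 1, starts + 30)
  aln <- mapReads(reads, ref, k = 10)
  cons <- callConsensus(removeDuplicates(aln), 100, circular = FALSE)
  cov3 <- cons$coverage >= 3
  expect_true(any(cov3))
  cc <- strsplit(as.character(cons$consensus), "")[[1]]
  expect_identical(cc[cov3], strsplit(rs, "")[[1]][cov3])
})

test_that("iterative assembly converges to the truth from a divergent reference", {
  truth <- simulateReference(4000, 0.4, seed = 49, id = "truth")
  init <- diverged_reference(truth, 0.05, seed = 50)
  sim <- simulateReadSet(truth, FragmentationModel(meanLength = 60,
                                                   coverageTarget = 30),
                         damage = NULL, seed = 51)
  asm <- iterateAssembly(sim$seq, init)
  expect_false(asm@failed)
  expect_gt(asm@iterations, 1)
  tv <- strsplit(as.character(truth@sequence), "")[[1]]
  cv <- strsplit(as.character(consensusSeq(asm)), "")[[1]]
  ok <- coverageTrack(asm) >= 3
  expect_identical(cv[ok], tv[ok])

  # consensus error is non-increasing across rounds: a single-pass result
  # is no closer to the truth than the converged one
  asm1 <- iterateAssembly(sim$seq, init,
                          params = ConsensusParams(maxIterations = 1))
  expect_equal(asm1@iterations, 1)
  dist_of <- function(a) {
    v <- strsplit(as.character(consensusSeq(a)), "")[[1]]
    sum(v != tv & v != "N")
  }
  expect_lte(dist_of(asm), dist_of(asm1))
})

test_that("assembly from the generating reference is a fixed point", {
  ref <- simulateReference(2000, 0.4, seed = 52)
  sim <- simulateReadSet(ref, FragmentationModel(meanLength = 60,
                                                 coverageTarget = 20),
                         damage = NULL, seed = 53)
  asm <- iterateAssembly(sim$seq, ref)
  expect_equal(asm@iterations, 2)  # one extra round confirms convergence
  ok <- coverageTrack(asm) >= 3
  expect_identical(strsplit(as.character(consensusSeq(asm)), "")[[1]][ok],
                   strsplit(as.character(ref@sequence), "")[[1]][ok])
})

test_that("unmappable read sets yield an explicit failed assembly", {
  ref <- simulateReference(2000, 0.4, seed = 54)
  junk <- replicate(20, random_seq(40))
  other <- simulateReference(2000, 0.4, seed = 999)
  reads <- vapply(seq(0, 1900, by = 100), function(s)
    decodeFragment(other, s, s + 40), character(1))
  asm <- iterateAssembly(reads, ref)
  expect_true(asm@failed)
  expect_equal(asm@uniqueFragments, 0)
})

test_that("coverage conservation: pileup depth sums to aligned bases", {
  ref <- simulateReference(1500, 0.4, seed = 55)
  sim <- simulateReadSet(ref, FragmentationModel(meanLength = 50,
                                                 coverageTarget = 8),
                         damage = NULL, seed = 56)
  aln <- removeDuplicates(mapReads(sim$seq, ref))
  cons <- callConsensus(aln, 1500)
  matched <- sum(vapply(aln$cigar, function(c) {
    ops <- regmatches(c, gregexpr("[0-9]+M", c))[[1]]
    sum(as.integer(sub("M", "", ops)))
  }, numeric(1)))
  expect_equal(sum(cons$coverage), matched)
})
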