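test_that("simulated references have forced length, GC content and seed determinism", {
  ref <- simulateReference(16500, gc = 0.4, seed = 1)
  expect_s4_class(ref, "ReferenceGenome")
  expect_equal(length(ref@sequence), 16500)
  gc <- mean(strsplit(as.character(ref@sequence), "")[[1]] %in% c("G", "C"))
  expect_lt(abs(gc - 0.4), 3 * sqrt(0.4 * 0.6 / 16500))

  at <- simulateReference(100, gc = 0, seed = 1)
  expect_false(grepl("[GC]", as.character(at@sequence)))

  a <- simulateReference(1000, gc = 0.5, seed = 7)
  b <- simulateReference(1000, gc = 0.5, seed = 7)
  expect_identical(as.character(a@sequence), as.character(b@sequence))

  expect_error(simulateReference(50, 0.4, 1), "length")
  expect_error(simulateReference(1000, 1.2, 1), "gc")
})

test_that("fragment simulation hits the coverage target, mean length and circular geometry", {
  ref <- simulateReference(16500, 0.4, seed = 2)
  frag <- FragmentationModel(meanLength = 60, coverageTarget = 30)
  fr <- simulateFragments(ref, frag, seed = 3)
  expect_equal(nrow(fr), 8250)                         # 30 * 16500 / 60
  expect_lt(abs(mean(fr$length) - 60) / 60, 0.05)
  expect_lt(abs(sum(fr$length) / 16500 - 30) / 30, 0.05)

  # wrap-around fragments decode to valid sequence of the right length
  wrap <- fr[fr$end > 16500, ]
  expect_gt(nrow(wrap), 0)
  s <- decodeFragment(ref, wrap$start[1], wrap$end[1])
  expect_equal(nchar(s), wrap$end[1] - wrap$start[1])
  expect_false(grepl("[^ACGT]", s))

  expect_identical(simulateFragments(ref, frag, seed = 5),
                   simulateFragments(ref, frag, seed = 5))
  expect_error(FragmentationModel(meanLength = 20, minLength = 30),
               "meanLength")
})

test_that("deamination follows the overhang model closed form", {
  # zero damage is the identity
  dm0 <- DamageModel(0.5, 0, 0, TRUE)
  seqs <- replicate(50, random_seq(40))
  out <- applyDamage(seqs, dm0, seed = 1)
  expect_identical(out$seq, seqs)
  expect_true(all(lengths(out$positions) == 0))

  # double-strand protocol, full deamination in overhangs covering the
  # terminal base: pooled 5'-terminal C->T tends to the 50% cap
  n <- 30000
  cfirst <- rep(paste0("C", random_seq(30)), n)
  dmax <- DamageModel(overhangDecay = 1, deltaSS = 1, deltaDS = 0,
                      bothStrands = TRUE)
  out <- applyDamage(cfirst, dmax, seed = 2)
  f <- mean(substring(out$seq, 1, 1) == "T")
  expect_lt(abs(f - 0.5), 3 * sqrt(0.25 / n))

  # single-strand protocol analogue: terminal deamination is complete
  dss <- DamageModel(overhangDecay = 1, deltaSS = 1, deltaDS = 0,
                     bothStrands = FALSE)
  out <- applyDamage(cfirst[1:2000], dss, seed = 3)
  expect_true(all(substring(out$seq, 1, 1) == "T"))

  # positional decay matches q^p * dss / 2 at interior positions
  dm <- DamageModel(overhangDecay = 0.6, deltaSS = 0.9, deltaDS = 0, TRUE)
  poly <- rep(strrep("C", 30), 40000)
  out <- applyDamage(poly, dm, seed = 4)
  for (p in c(1, 2, 4)) {
    f <- mean(substring(out$seq, p, p) == "T")
    exp_f <- expectedTerminalFrequency(dm, p)
    expect_lt(abs(f - exp_f), 3 * sqrt(exp_f * (1 - exp_f) / 40000))
  }

  # ground truth records exactly the altered positions
  out <- applyDamage(seqs, dm, seed = 5)
  for (i in seq_along(seqs)) {
    diffs <- which(strsplit(seqs[i], "")[[1]] != strsplit(out$seq[i], "")[[1]])
    expect_identical(diffs, as.integer(out$positions[[i]]))
  }
})

test_that("emitted FASTQ pairs parse, pair up and obey read-through geometry", {
  ref <- simulateReference(2000, 0.4, seed = 6)
  sim <- simulateReadSet(ref, FragmentationModel(meanLength = 60,
                                                 coverageTarget = 1),
                         damage = NULL, seed = 7, n = 10)
  f1 <- tempfile(fileext = ".fastq"); f2 <- tempfile(fileext = ".fastq")
  emitFastqPairs(sim$seq, readLength = 100, errorRate = 0,
                 out1 = f1, out2 = f2, seed = 8)
  r1 <- readFastq(f1); r2 <- readFastq(f2)
  expect_equal(nrow(r1), 10)
  expect_equal(nrow(r2), 10)
  expect_identical(r1$id, r2$id)
  expect_true(all(nchar(r1$seq) == 100))
  # error-free mate 1 starts with the fragment, mate 2 with its revcomp
  for (i in 1:10) {
    n <- min(nchar(sim$seq[i]), 100)
    expect_identical(substr(r1$seq[i], 1, n), substr(sim$seq[i], 1, n))
    expect_identical(substr(r2$seq[i], 1, n),
                     substr(revcomp(sim$seq[i]), 1, n))
  }
  # fragments shorter than the read carry adapter suffix on both mates
  short <- which(nchar(sim$seq) < 100)[1]
  expect_match(substring(r1$seq[short], nchar(sim$seq[short]) + 1),
               "^AGATCGGAAGAGC")
})

test_that("alignment simulation matches the JC closed form and is reproducible", {
  tr <- ape::read.tree(text = "(a:0.05,b:0.05);")
  jc <- PhyloModel(nCategories = 1, gammaShape = 1)
  aln <- simulateAlignmentOnTree(tr, jc, 100000, seed = 3)
  p <- mean(aln["a", ] != aln["b", ])
  expected <- 0.75 * (1 - exp(-4 * 0.1 / 3))
  expect_lt(abs(p - expected), 3 * sqrt(expected * (1 - expected) / 1e5))

  tr0 <- ape::read.tree(text = "((a:0,b:0):0,(c:0,d:0):0);")
  aln0 <- simulateAlignmentOnTree(tr0, jc, 200, seed = 4)
  expect_true(all(apply(aln0, 2, function(col) length(unique(col)) == 1)))

  expect_identical(simulateAlignmentOnTree(tr, jc, 100, seed = 9),
                   simulateAlignmentOnTree(tr, jc, 100, seed = 9))

  multi <- ape::read.tree(text = "(a:1,b:1,c:1,d:1);")
  expect_error(simulateAlignmentOnTree(multi, jc, 10, seed = 1), "binary")
})

test_that("isotope simulation reproduces group means and the invalid C/N fraction", {
  g1 <- data.frame(taxon = "Rangifer", period = "pre-LGM",
                   meanD13C = -18.5, meanD15N = 3,
                   sdD13C = 0, sdD15N = 0, n = 5)
  t1 <- simulateIsotopeTable(g1, seed = 1, analyticNoise = c(0, 0))
  expect_true(all(t1$d13C == -18.5) && all(t1$d15N == 3))

  g2 <- data.frame(taxon = "Cervus", period = "late-glacial",
                   meanD13C = -20, meanD15N = 4.5,
                   sdD13C = 0.5, sdD15N = 0.5, n = 1000)
  t2 <- simulateIsotopeTable(g2, seed = 2, invalidFraction = 0.1)
  bad <- sum(cnAtomic(t2$pctC, t2$pctN) < 2.9 |
             cnAtomic(t2$pctC, t2$pctN) > 3.6)
  expect_lt(abs(bad - 100), 3 * sqrt(1000 * 0.1 * 0.9))

  expect_identical(simulateIsotopeTable(g2, seed = 5),
                   simulateIsotopeTable(g2, seed = 5))
  expect_error(simulateIsotopeTable(g2[0, ], seed = 1), "non-empty")
})
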