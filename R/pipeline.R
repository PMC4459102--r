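# End-to-end orchestration: simulate -> emit FASTQ -> merge -> assemble ->
# authenticate (-> isotopes), with stage outputs persisted under a run
# directory and a machine-readable JSON report.

#' Build a pipeline run configuration
#'
#' Defaults mirror the standard ancient mtDNA processing constants: merge
#' overlap >= 11 bp, merged length >= 30 bp, consensus coverage >= 3-fold,
#' authentication threshold 20%, 5 gamma categories with shape 0.3366,
#' 1000 bootstrap replicates, collagen C/N window 2.9-3.6.
#'
#' @param seed global seed; per-stage seeds are derived from it.
#' @param outDir run directory for stage outputs.
#' @param refLength,gc simulated reference length and GC fraction.
#' @param fragmentation a [FragmentationModel-class].
#' @param damage a [DamageModel-class], or NULL for an undamaged
#'   (blank-like) library.
#' @param nFragments explicit fragment count (NULL: from coverage target).
#' @param readLength,errorRate sequencing simulation parameters.
#' @param merge a [MergeParams-class].
#' @param consensus a [ConsensusParams-class].
#' @param damageThreshold authentication threshold.
#' @param damageK terminal positions profiled.
#' @param phyloModel a [PhyloModel-class].
#' @param nBootstrap bootstrap replicates for optional tree building.
#' @param qc a [QCParams-class].
#' @param isotopeGroups optional group table for isotope simulation.
#' @return a named list (class `"amRunConfig"`).
#' @export
runConfig <- function(seed = 1, outDir = tempfile("am_run_"),
                      refLength = 16500, gc = 0.4,
                      fragmentation = FragmentationModel(),
                      damage = DamageModel(),
                      nFragments = NULL,
                      readLength = 100, errorRate = 0,
                      merge = MergeParams(),
                      consensus = ConsensusParams(),
                      damageThreshold = 0.20, damageK = 25,
                      phyloModel = PhyloModel(),
                      nBootstrap = 1000,
                      qc = QCParams(),
                      isotopeGroups = NULL) {
  cfg <- list(seed = seed, outDir = outDir, refLength = refLength, gc = gc,
              fragmentation = fragmentation, damage = damage,
              nFragments = nFragments, readLength = readLength,
              errorRate = errorRate, merge = merge, consensus = consensus,
              damageThreshold = damageThreshold, damageK = damageK,
              phyloModel = phyloModel, nBootstrap = nBootstrap, qc = qc,
              isotopeGroups = isotopeGroups)
  class(cfg) <- c("amRunConfig", "list")
  cfg
}

config_echo <- function(cfg) {
  list(seed = cfg$seed, refLength = cfg$refLength, gc = cfg$gc,
       meanFragmentLength = cfg$fragmentation@meanLength,
       coverageTarget = cfg$fragmentation@coverageTarget,
       damage = if (is.null(cfg$damage)) NULL else list(
         overhangDecay = cfg$damage@overhangDecay,
         deltaSS = cfg$damage@deltaSS, deltaDS = cfg$damage@deltaDS,
         bothStrands = cfg$damage@bothStrands),
       readLength = cfg$readLength, errorRate = cfg$errorRate,
       minOverlap = cfg$merge@minOverlap,
       minMergedLength = cfg$merge@minLength,
       minCoverage = cfg$consensus@minCoverage,
       damageThreshold = cfg$damageThreshold,
       gammaShape = cfg$phyloModel@gammaShape,
       gammaCategories = cfg$phyloModel@nCategories,
       nBootstrap = cfg$nBootstrap,
       cnRange = c(cfg$qc@cnMin, cfg$qc@cnMax))
}

#' Run the simulation-to-authentication pipeline
#'
#' Simulates an ancient library from a synthetic circular reference, emits
#' and merges paired FASTQ reads, assembles a coverage-masked consensus by
#' iterative damage-aware mapping, profiles terminal misincorporations
#' against the consensus, and applies the authenticity rule. Stage outputs
#' (FASTQ, FASTA, TSV, JSON) are written under `config$outDir`; any stage
#' failure is recorded in the report and later stages are skipped.
#'
#' @param config a configuration from [runConfig()].
#' @return the report (named list, also written to `report.json`).
#' @export
runPipeline <- function(config) {
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  path <- function(f) file.path(config$outDir, f)
  report <- list(config = config_echo(config),
                 stages = list(), timestamp = format(Sys.time()))
  fail <- function(stage, err) {
    report$stages[[stage]] <<- list(status = "failed",
                                    error = conditionMessage(err))
  }
  done <- function(stage) report$stages[[stage]] <<- list(status = "ok")

  sim <- NULL; ref <- NULL
  tryCatch({
    ref <- simulateReference(config$refLength, config$gc,
                             derive_seed(config$seed, 1))
    sim <- simulateReadSet(ref, config$fragmentation, config$damage,
                           seed = derive_seed(config$seed, 2),
                           n = config$nFragments)
    emitFastqPairs(sim$seq, readLength = config$readLength,
                   errorRate = config$errorRate,
                   out1 = path("reads_R1.fastq"),
                   out2 = path("reads_R2.fastq"),
                   seed = derive_seed(config$seed, 3))
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(setNames(as.character(ref@sequence),
                                        ref@id)),
      path("reference.fasta"))
    done("simulate")
  }, error = function(e) fail("simulate", e))
  if (is.null(sim)) return(finish_report(report, config))

  merged <- NULL
  tryCatch({
    merged <- mergeFastq(path("reads_R1.fastq"), path("reads_R2.fastq"),
                         out = path("merged.fastq"),
                         statsOut = path("merge_stats.tsv"),
                         params = config$merge)
    report$merge <- as.list(merged$log)
    done("merge")
  }, error = function(e) fail("merge", e))
  if (is.null(merged)) return(finish_report(report, config))

  asm <- NULL
  tryCatch({
    res <- iterateAssembly(merged$retained$seq, ref,
                           quals = merged$retained$qual,
                           ids = merged$retained$id,
                           params = config$consensus)
    if (res@failed) stop("assembly failed: no reads mapped in round 1")
    asm <- res
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(setNames(as.character(asm@consensus),
                                        "consensus")),
      path("consensus.fasta"))
    write.table(data.frame(pos = seq_along(asm@coverage),
                           depth = asm@coverage),
                path("coverage.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    st <- assemblyStats(asm, totalMergedReads = merged$log[["retained"]])
    write.table(st, path("assembly_stats.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    report$assembly <- as.list(st)
    done("assemble")
  }, error = function(e) fail("assemble", e))
  if (is.null(asm)) return(finish_report(report, config))

  tryCatch({
    prof <- profileDamage(asm@alignments, asm@consensus, K = config$damageK)
    writeMisincorporation(prof, path("misincorporation.tsv"))
    verdict <- authenticate(prof, threshold = config$damageThreshold)
    report$damage <- list(
      c2t_5prime_pct = 100 * verdict@c2t5prime,
      g2a_3prime_pct = 100 * verdict@g2a3prime,
      threshold_pct = 100 * verdict@threshold,
      authentic = verdict@authentic)
    jsonlite::write_json(report$damage, path("verdict.json"),
                         auto_unbox = TRUE, digits = NA)
    done("authenticate")
  }, error = function(e) fail("authenticate", e))

  if (!is.null(config$isotopeGroups)) {
    tryCatch({
      iso <- simulateIsotopeTable(config$isotopeGroups,
                                  derive_seed(config$seed, 5))
      write.table(iso, path("isotopes.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
      qcres <- qcFilter(iso, config$qc)
      report$isotopes <- list(total = nrow(iso),
                              retained = nrow(qcres$retained),
                              rejected = nrow(qcres$rejected))
      done("isotopes")
    }, error = function(e) fail("isotopes", e))
  }
  finish_report(report, config)
}

finish_report <- function(report, config) {
  jsonlite::write_json(report,
                       file.path(config$outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(report)
}
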