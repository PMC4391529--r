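#' @import methods
#' @importFrom BiocGenerics score
#' @importFrom stats rnorm rlnorm sd aggregate oneway.test t.test pf pt setNames
#' @importFrom utils write.table read.delim
NULL

#' Simulation settings for synthetic multi-omics inputs
#'
#' Holds every knob of the synthetic-data generators: the planted-truth
#' genome pair for the ortholog screen, the probe-level two-color ratio
#' table, the 2D-gel spot-volume table, the GC-MS peak-area table and the
#' functional annotation. Defaults reproduce the study conditions the
#' analysis modules assume: three biological replicates, 9-11 probes per
#' gene spanning -300..+200 around the translational start, a two-fold
#' (log2 = 2) planted expression effect, and planted orthologs spread over
#' 40-100 percent identity at protein lengths of at least 200 residues.
#'
#' @slot seed integer RNG seed; every generator derives its stream from it
#'   so a fixed seed yields byte-identical outputs.
#' @slot nGenes number of genes in the probe table and annotation.
#' @slot nProbesPerGene integer range (min, max) of probes per gene.
#' @slot probeWindow integer window (bp) of probe midpoints relative to the
#'   translational start at +1; position 0 does not exist.
#' @slot nReplicates biological replicates per condition.
#' @slot deFractionUp,deFractionDown fractions of genes planted up / down
#'   per stress condition.
#' @slot deEffect planted shift in log2 units.
#' @slot probeNoiseSd per-probe Gaussian noise sd in log2 units.
#' @slot nSpots number of gel spots.
#' @slot nPlantedSpots number of spots carrying a planted fold change.
#' @slot spotCv coefficient of variation of spot volumes across replicates.
#' @slot plantedSpotFold multiplicative fold applied to planted spots under
#'   both stress conditions.
#' @slot peakCv coefficient of variation of GC-MS analyte peak areas.
#' @slot orthologIdentityLevels target identities of planted orthologs, one
#'   planted pair per level, each in (0, 1].
#' @slot orthologLengthRange integer range of planted protein lengths.
#' @slot decoyCount number of unrelated random proteins added to the target
#'   proteome (absent from the truth table).
#'
#' @seealso [simulateGenomePair()], [simulateProbeTable()],
#'   [simulateSpotTable()], [simulatePeakTable()], [simulateAnnotation()]
#' @export
setClass("SimulationConfig",
  representation(
    seed = "integer",
    nGenes = "integer",
    nProbesPerGene = "integer",
    probeWindow = "integer",
    nReplicates = "integer",
    deFractionUp = "numeric",
    deFractionDown = "numeric",
    deEffect = "numeric",
    probeNoiseSd = "numeric",
    nSpots = "integer",
    nPlantedSpots = "integer",
    spotCv = "numeric",
    plantedSpotFold = "numeric",
    peakCv = "numeric",
    orthologIdentityLevels = "numeric",
    orthologLengthRange = "integer",
    decoyCount = "integer"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@deFractionUp < 0 || object@deFractionDown < 0)
    msg <- c(msg, "DE fractions must be non-negative")
  if (object@deFractionUp + object@deFractionDown > 1)
    msg <- c(msg, "deFractionUp + deFractionDown must not exceed 1")
  if (any(object@orthologIdentityLevels <= 0) ||
      any(object@orthologIdentityLevels > 1))
    msg <- c(msg, "ortholog identity levels must lie in (0, 1]")
  if (length(object@probeWindow) != 2L ||
      object@probeWindow[1] >= object@probeWindow[2])
    msg <- c(msg, "probeWindow must be an increasing (lo, hi) pair")
  if (object@nReplicates < 2L)
    msg <- c(msg, "at least two replicates are required")
  if (object@probeNoiseSd < 0 || object@spotCv < 0 || object@peakCv < 0)
    msg <- c(msg, "noise parameters must be non-negative")
  if (object@plantedSpotFold <= 0)
    msg <- c(msg, "plantedSpotFold must be positive")
  if (object@nPlantedSpots > object@nSpots)
    msg <- c(msg, "nPlantedSpots cannot exceed nSpots")
  if (length(msg)) msg else TRUE
})

#' @param seed,nGenes,nProbesPerGene,probeWindow,nReplicates,deFractionUp,deFractionDown,deEffect,probeNoiseSd,nSpots,nPlantedSpots,spotCv,plantedSpotFold,peakCv,orthologIdentityLevels,orthologLengthRange,decoyCount
#'   see the corresponding slots.
#' @return `SimulationConfig()` returns a validated configuration object.
#' @examples
#' cfg <- SimulationConfig(seed = 7, nGenes = 50)
#' cfg
#' @rdname SimulationConfig-class
#' @export
SimulationConfig <- function(seed = 1L,
                             nGenes = 200L,
                             nProbesPerGene = c(9L, 11L),
                             probeWindow = c(-300L, 200L),
                             nReplicates = 3L,
                             deFractionUp = 0.10,
                             deFractionDown = 0.075,
                             deEffect = 2.0,
                             probeNoiseSd = 0.2,
                             nSpots = 300L,
                             nPlantedSpots = 20L,
                             spotCv = 0.2,
                             plantedSpotFold = 3.0,
                             peakCv = 0.2,
                             orthologIdentityLevels =
                               seq(0.4, 1.0, length.out = 50L),
                             orthologLengthRange = c(200L, 400L),
                             decoyCount = 20L) {
  new("SimulationConfig",
    seed = as.integer(seed),
    nGenes = as.integer(nGenes),
    nProbesPerGene = as.integer(nProbesPerGene),
    probeWindow = as.integer(probeWindow),
    nReplicates = as.integer(nReplicates),
    deFractionUp = deFractionUp,
    deFractionDown = deFractionDown,
    deEffect = deEffect,
    probeNoiseSd = probeNoiseSd,
    nSpots = as.integer(nSpots),
    nPlantedSpots = as.integer(nPlantedSpots),
    spotCv = spotCv,
    plantedSpotFold = plantedSpotFold,
    peakCv = peakCv,
    orthologIdentityLevels = orthologIdentityLevels,
    orthologLengthRange = as.integer(orthologLengthRange),
    decoyCount = as.integer(decoyCount)
  )
}

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig\n")
  cat("  seed:", object@seed, "\n")
  cat("  genes:", object@nGenes, " probes/gene:",
      paste(object@nProbesPerGene, collapse = "-"),
      " window:", paste(object@probeWindow, collapse = ".."), "\n")
  cat("  replicates:", object@nReplicates,
      " DE up/down:", object@deFractionUp, "/", object@deFractionDown,
      " effect:", object@deEffect, "log2  noise sd:",
      object@probeNoiseSd, "\n")
  cat("  spots:", object@nSpots, " planted:", object@nPlantedSpots,
      " fold:", object@plantedSpotFold, " cv:", object@spotCv, "\n")
  cat("  peak cv:", object@peakCv, "\n")
  cat("  planted orthologs:", length(object@orthologIdentityLevels),
      " identity:", sprintf("%.2f-%.2f",
        min(object@orthologIdentityLevels),
        max(object@orthologIdentityLevels)),
      " decoys:", object@decoyCount, "\n")
})

#' Parameters of the reciprocal best-hit ortholog screen
#'
#' Scoring and acceptance parameters for the Smith-Waterman based screen:
#' substitution matrix, affine gap penalties, the minimum local alignment
#' score and the minimum fraction of the hit sequence that must be covered
#' by the alignment. The defaults follow the screen's published thresholds
#' (score 100, 75 percent overlap) with BLOSUM62 and gap open 11 /
#' extend 1, the most widely reproduced protein alignment defaults.
#'
#' @slot substitutionMatrix name of a substitution matrix shipped with
#'   Biostrings (e.g. "BLOSUM62", "BLOSUM50", "PAM250").
#' @slot gapOpen,gapExtend affine gap penalties; a gap of length L costs
#'   `gapOpen + L * gapExtend`.
#' @slot minScore minimum Smith-Waterman score for a hit.
#' @slot minOverlap minimum fraction of the hit (subject) length covered
#'   by the local alignment.
#' @export
setClass("ScreenConfig",
  representation(
    substitutionMatrix = "character",
    gapOpen = "numeric",
    gapExtend = "numeric",
    minScore = "numeric",
    minOverlap = "numeric"
  )
)

setValidity("ScreenConfig", function(object) {
  msg <- character()
  if (object@minScore <= 0) msg <- c(msg, "minScore must be positive")
  if (object@minOverlap <= 0 || object@minOverlap > 1)
    msg <- c(msg, "minOverlap must lie in (0, 1]")
  if (object@gapOpen < 0 || object@gapExtend < 0)
    msg <- c(msg, "gap penalties must be non-negative")
  if (length(msg)) msg else TRUE
})

#' @param substitutionMatrix,gapOpen,gapExtend,minScore,minOverlap see slots.
#' @return `ScreenConfig()` returns a validated configuration object.
#' @examples
#' ScreenConfig(minScore = 80)
#' @rdname ScreenConfig-class
#' @export
ScreenConfig <- function(substitutionMatrix = "BLOSUM62",
                         gapOpen = 11, gapExtend = 1,
                         minScore = 100, minOverlap = 0.75) {
  new("ScreenConfig",
    substitutionMatrix = substitutionMatrix,
    gapOpen = gapOpen, gapExtend = gapExtend,
    minScore = minScore, minOverlap = minOverlap
  )
}

setMethod("show", "ScreenConfig", function(object) {
  cat("ScreenConfig:", object@substitutionMatrix,
      sprintf("gap %g/%g, min score %g, min overlap %g\n",
              object@gapOpen, object@gapExtend,
              object@minScore, object@minOverlap))
})

#' A scored local protein alignment
#'
#' Result of [smithWaterman()]: the optimal local alignment score under
#' affine gap penalties, the fraction of identical columns (gap columns
#' included in the denominator), the aligned spans on query and subject,
#' and the fraction of the subject covered by the alignment.
#'
#' @slot score optimal local alignment score (substitution-matrix units).
#' @slot identity identical aligned columns divided by total alignment
#'   columns, gap columns included.
#' @slot queryStart,queryEnd,subjectStart,subjectEnd 1-based closed aligned
#'   spans; all zero for an empty (score 0) alignment.
#' @slot overlapFraction subject-aligned length divided by subject length.
#' @slot subjectId id of the subject sequence (NA when aligned ad hoc).
#' @export
setClass("AlignmentResult",
  representation(
    score = "numeric",
    identity = "numeric",
    queryStart = "integer",
    queryEnd = "integer",
    subjectStart = "integer",
    subjectEnd = "integer",
    overlapFraction = "numeric",
    subjectId = "character"
  )
)

setValidity("AlignmentResult", function(object) {
  msg <- character()
  if (object@score < 0) msg <- c(msg, "score must be >= 0")
  if (object@identity < 0 || object@identity > 1)
    msg <- c(msg, "identity must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "AlignmentResult", function(object) {
  cat(sprintf(
    "AlignmentResult: score %g, identity %.3f, overlap %.3f, q[%d..%d] s[%d..%d]%s\n",
    object@score, object@identity, object@overlapFraction,
    object@queryStart, object@queryEnd,
    object@subjectStart, object@subjectEnd,
    if (is.na(object@subjectId)) "" else paste0(" hit=", object@subjectId)))
})

#' @describeIn AlignmentResult-class the Smith-Waterman score.
#' @param x,object an `AlignmentResult`.
#' @export
setMethod("score", "AlignmentResult", function(x, ...) x@score)

#' Extract the identity fraction of an alignment or presence call
#'
#' @param x an object carrying an identity fraction.
#' @return numeric identity in \[0, 1\].
#' @export
setGeneric("identityFraction", function(x) standardGeneric("identityFraction"))

#' @rdname identityFraction
#' @export
setMethod("identityFraction", "AlignmentResult", function(x) x@identity)

#' Extract the subject-overlap fraction of an alignment
#'
#' @param x an `AlignmentResult`.
#' @return numeric fraction of the subject sequence covered.
#' @export
setGeneric("overlapFraction", function(x) standardGeneric("overlapFraction"))

#' @rdname overlapFraction
#' @export
setMethod("overlapFraction", "AlignmentResult", function(x) x@overlapFraction)

#' Presence/absence matrix of seed genes across organisms
#'
#' One cell per (seed gene, organism): `present` when the reciprocal
#' best-hit criterion holds, with the identity of the forward alignment;
#' `absent` (identity NA) otherwise. Rows keep the seed panel order,
#' columns the organism order.
#'
#' @slot seeds seed gene ids (rows).
#' @slot organisms organism codes (columns).
#' @slot status character matrix, "present"/"absent".
#' @slot identity numeric matrix of forward-alignment identities, NA where
#'   absent.
#' @slot hits character matrix of target locus ids, NA where absent.
#' @seealso [buildPresenceMatrix()], [writePresenceMatrix()],
#'   [renderPresenceHeatmap()]
#' @export
setClass("PresenceMatrix",
  representation(
    seeds = "character",
    organisms = "character",
    status = "matrix",
    identity = "matrix",
    hits = "matrix"
  )
)

setValidity("PresenceMatrix", function(object) {
  msg <- character()
  d <- c(length(object@seeds), length(object@organisms))
  for (s in c("status", "identity", "hits"))
    if (!identical(dim(slot(object, s)), d))
      msg <- c(msg, paste(s, "matrix dimensions must match seeds x organisms"))
  bad <- !(object@status %in% c("present", "absent"))
  if (any(bad)) msg <- c(msg, "status cells must be 'present' or 'absent'")
  if (any((object@status == "present") != !is.na(object@identity)))
    msg <- c(msg, "identity must be populated exactly where status is present")
  if (length(msg)) msg else TRUE
})

setMethod("show", "PresenceMatrix", function(object) {
  cat(sprintf("PresenceMatrix: %d seed genes x %d organisms, %d present\n",
              length(object@seeds), length(object@organisms),
              sum(object@status == "present")))
})

#' @describeIn PresenceMatrix-class number of (seed, organism) cells.
#' @param x a `PresenceMatrix`.
#' @export
setMethod("length", "PresenceMatrix", function(x) length(x@status))

#' Tidy view of a presence matrix
#'
#' @param x a `PresenceMatrix`.
#' @return data.frame with one row per (seed, organism) call: `seed_id`,
#'   `organism`, `status`, `identity`, `hit_id`.
#' @export
presenceCalls <- function(x) {
  stopifnot(is(x, "PresenceMatrix"))
  data.frame(
    seed_id = rep(x@seeds, times = length(x@organisms)),
    organism = rep(x@organisms, each = length(x@seeds)),
    status = as.vector(x@status),
    identity = as.vector(x@identity),
    hit_id = as.vector(x@hits),
    stringsAsFactors = FALSE
  )
}

#' Differential-expression caller settings
#'
#' The replicate-consistent fold-change rule: a gene is called up (down)
#' when its per-replicate mean log2 ratio exceeds +threshold (falls below
#' -threshold) in all replicates. Comparisons are strict inequalities.
#'
#' @slot threshold log2 cut-off (default 1, i.e. two-fold).
#' @slot nReplicates expected number of biological replicates (default 3).
#' @slot requireAll when TRUE (default) the rule must hold in every
#'   replicate; when FALSE a majority of replicates suffices.
#' @export
setClass("DEConfig",
  representation(
    threshold = "numeric",
    nReplicates = "integer",
    requireAll = "logical"
  )
)

setValidity("DEConfig", function(object) {
  if (object@threshold <= 0) "threshold must be positive" else TRUE
})

#' @param threshold,nReplicates,requireAll see slots.
#' @return `DEConfig()` returns a validated configuration object.
#' @examples
#' DEConfig(threshold = 1)
#' @rdname DEConfig-class
#' @export
DEConfig <- function(threshold = 1, nReplicates = 3L, requireAll = TRUE) {
  new("DEConfig", threshold = threshold,
      nReplicates = as.integer(nReplicates), requireAll = requireAll)
}

setMethod("show", "DEConfig", function(object) {
  cat(sprintf("DEConfig: |log2| > %g in %s of %d replicates\n",
              object@threshold,
              if (object@requireAll) "all" else "a majority",
              object@nReplicates))
})
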