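# Synthetic inputs with planted ground truth. Each generator derives its RNG
# stream from config@seed plus a generator-specific offset, so streams are
# independent across generators but byte-identical across runs.

.AA20 <- c("A","R","N","D","C","Q","E","G","H","I",
           "L","K","M","F","P","S","T","W","Y","V")

.withSeed <- function(seed, offset, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed((seed + offset) %% .Machine$integer.max)
  expr
}

.randomProtein <- function(len) paste(sample(.AA20, len, replace = TRUE), collapse = "")

# substitute exactly k positions, always to a different residue
.mutateProtein <- function(seqchars, k) {
  if (k == 0L) return(seqchars)
  pos <- sample(length(seqchars), k)
  for (p in pos) {
    seqchars[p] <- sample(setdiff(.AA20, seqchars[p]), 1L)
  }
  seqchars
}

# multiplicative lognormal noise with unit mean at the given cv
.lognoise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(rnorm(n, mean = -sdlog^2 / 2, sd = sdlog))
}

#' Simulate a pair of proteomes with planted orthologs
#'
#' Builds a source proteome of random proteins and a target proteome that
#' contains, for each identity level in the configuration, a point-mutated
#' copy of the corresponding source protein (substitutions only, so the
#' realized identity is exactly `(L - k) / L` for `k` mutated positions),
#' plus `decoyCount` unrelated random proteins that never appear in the
#' truth table. This emulates the organism pairs screened for
#' osmolyte-gene presence.
#'
#' @param config a [SimulationConfig].
#' @return list with elements `source` and `target`
#'   ([Biostrings::AAStringSet] with sequence ids as names) and `truth`, a
#'   data.frame (`seed_id`, `target_id`, `target_identity`,
#'   `realized_identity`, `length`).
#' @examples
#' gp <- simulateGenomePair(SimulationConfig(seed = 1,
#'   orthologIdentityLevels = c(0.5, 0.8, 1.0), decoyCount = 2))
#' gp$truth
#' @export
simulateGenomePair <- function(config = SimulationConfig()) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  levels <- config@orthologIdentityLevels
  .withSeed(config@seed, 101L, {
    nOrth <- length(levels)
    lens <- sample(seq(config@orthologLengthRange[1],
                       config@orthologLengthRange[2]), nOrth, replace = TRUE)
    srcIds <- sprintf("SRC_%03d", seq_len(nOrth))
    tgtIds <- sprintf("TGT_%03d", seq_len(nOrth))
    src <- character(nOrth); tgt <- character(nOrth); realized <- numeric(nOrth)
    for (i in seq_len(nOrth)) {
      chars <- sample(.AA20, lens[i], replace = TRUE)
      src[i] <- paste(chars, collapse = "")
      k <- round((1 - levels[i]) * lens[i])
      tgt[i] <- paste(.mutateProtein(chars, k), collapse = "")
      realized[i] <- (lens[i] - k) / lens[i]
    }
    decoys <- character(config@decoyCount)
    if (config@decoyCount > 0) {
      dlens <- sample(seq(config@orthologLengthRange[1],
                          config@orthologLengthRange[2]),
                      config@decoyCount, replace = TRUE)
      decoys <- vapply(dlens, .randomProtein, character(1))
      names(decoys) <- sprintf("DEC_%03d", seq_len(config@decoyCount))
    }
    sourceSet <- Biostrings::AAStringSet(setNames(src, srcIds))
    targetSet <- Biostrings::AAStringSet(c(setNames(tgt, tgtIds), decoys))
    list(
      source = sourceSet,
      target = targetSet,
      truth = data.frame(
        seed_id = srcIds, target_id = tgtIds,
        target_identity = levels, realized_identity = realized,
        length = lens, stringsAsFactors = FALSE
      )
    )
  })
}

.CONTRASTS <- c("NaCl_vs_control", "sucrose_vs_control", "sucrose_vs_NaCl")

#' Simulate a probe-level two-color log2-ratio table
#'
#' Emulates the probe-level output of a custom tiling design with 9-11
#' probes per gene whose midpoints fall in a window around the
#' translational start (+1); upstream probes carry negative offsets.
#' Per-condition truth is planted as a log2 shift of `deEffect` applied to
#' every probe in every replicate; the direct sucrose-vs-NaCl contrast is
#' the difference of the two planted condition effects. Non-planted genes
#' fluctuate around 0 with Gaussian noise of sd `probeNoiseSd`.
#'
#' @param config a [SimulationConfig].
#' @return list with `probes` (data.frame `probe_id`, `gene_id`, `offset`,
#'   `contrast`, `rep1..repK`) and `truth` (data.frame `gene_id`,
#'   `contrast`, `direction` in up/down/none, `effect` in log2 units).
#' @examples
#' pt <- simulateProbeTable(SimulationConfig(seed = 1, nGenes = 20))
#' head(pt$probes)
#' @export
simulateProbeTable <- function(config = SimulationConfig()) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  .withSeed(config@seed, 202L, {
    n <- config@nGenes
    genes <- sprintf("gene_%04d", seq_len(n))
    nUp <- round(config@deFractionUp * n)
    nDown <- round(config@deFractionDown * n)
    effectFor <- function() {
      idx <- sample(n, nUp + nDown)
      eff <- numeric(n)
      eff[idx[seq_len(nUp)]] <- config@deEffect
      if (nDown > 0) eff[idx[nUp + seq_len(nDown)]] <- -config@deEffect
      eff
    }
    effNaCl <- effectFor()
    effSuc <- effectFor()
    effDirect <- effSuc - effNaCl
    eff <- cbind(NaCl_vs_control = effNaCl,
                 sucrose_vs_control = effSuc,
                 sucrose_vs_NaCl = effDirect)

    offsetsAllowed <- setdiff(seq(config@probeWindow[1], config@probeWindow[2]), 0L)
    nProbes <- sample(seq(config@nProbesPerGene[1], config@nProbesPerGene[2]),
                      n, replace = TRUE)
    rows <- vector("list", n)
    reps <- paste0("rep", seq_len(config@nReplicates))
    for (g in seq_len(n)) {
      off <- sort(sample(offsetsAllowed, nProbes[g]))
      base <- data.frame(
        probe_id = sprintf("%s_p%02d", genes[g], seq_len(nProbes[g])),
        gene_id = genes[g], offset = off, stringsAsFactors = FALSE
      )
      perContrast <- lapply(.CONTRASTS, function(ct) {
        b <- base
        b$contrast <- ct
        m <- matrix(eff[g, ct] +
                      rnorm(nProbes[g] * config@nReplicates,
                            sd = config@probeNoiseSd),
                    nrow = nProbes[g])
        colnames(m) <- reps
        cbind(b, as.data.frame(m))
      })
      rows[[g]] <- do.call(rbind, perContrast)
    }
    probes <- do.call(rbind, rows)
    rownames(probes) <- NULL
    truth <- data.frame(
      gene_id = rep(genes, times = length(.CONTRASTS)),
      contrast = rep(.CONTRASTS, each = n),
      effect = as.vector(eff),
      stringsAsFactors = FALSE
    )
    truth$direction <- ifelse(truth$effect > 0, "up",
                              ifelse(truth$effect < 0, "down", "none"))
    list(probes = probes, truth = truth)
  })
}

#' Simulate a 2D-gel spot-volume table
#'
#' Draws per-spot base abundances on a lognormal scale and plants a
#' multiplicative fold change on `nPlantedSpots` spots under both stress
#' conditions. Each gel's raw total is held constant by redistributing the
#' planted surplus proportionally over the non-planted spots - mimicking
#' pulse-labeling with a fixed total label incorporation - so that after
#' normalization to total gel quantity the planted spots show exactly the
#' planted fold at zero noise. Replicate noise is lognormal with unit mean
#' at coefficient of variation `spotCv`.
#'
#' @param config a [SimulationConfig].
#' @return list with `spots` (data.frame `gel_id`, `condition`,
#'   `replicate`, `spot_id`, `raw_volume`) and `truth` (data.frame
#'   `spot_id`, `planted`, `fold`).
#' @examples
#' st <- simulateSpotTable(SimulationConfig(seed = 1, nSpots = 30,
#'   nPlantedSpots = 3, spotCv = 0))
#' head(st$spots)
#' @export
simulateSpotTable <- function(config = SimulationConfig()) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  .withSeed(config@seed, 303L, {
    n <- config@nSpots
    spotIds <- sprintf("spot_%04d", seq_len(n))
    base <- rlnorm(n, meanlog = log(1000), sdlog = 1)
    planted <- sort(sample(n, config@nPlantedSpots))
    isPlanted <- seq_len(n) %in% planted
    fold <- config@plantedSpotFold
    total <- sum(base)
    shrink <- (total - fold * sum(base[isPlanted])) /
              (total - sum(base[isPlanted]))
    if (shrink <= 0)
      stop("planted surplus exhausts the gel total; lower fold or planted count")
    meansFor <- function(condition) {
      if (condition == "control") return(base)
      ifelse(isPlanted, base * fold, base * shrink)
    }
    conditions <- c("control", "NaCl", "sucrose")
    rows <- list()
    for (cond in conditions) {
      mu <- meansFor(cond)
      for (r in seq_len(config@nReplicates)) {
        vol <- mu * .lognoise(n, config@spotCv)
        rows[[paste(cond, r)]] <- data.frame(
          gel_id = sprintf("%s_r%d", cond, r),
          condition = cond, replicate = r,
          spot_id = spotIds, raw_volume = vol,
          stringsAsFactors = FALSE
        )
      }
    }
    spots <- do.call(rbind, rows)
    rownames(spots) <- NULL
    list(
      spots = spots,
      truth = data.frame(
        spot_id = spotIds, planted = isPlanted,
        fold = ifelse(isPlanted, fold, shrink),
        stringsAsFactors = FALSE
      )
    )
  })
}

#' Printed condition means of the metabolites changed under osmotic stress
#'
#' The six metabolites reported as significantly changed after NaCl or
#' sucrose upshift, with their mean relative quantities (analyte peak area
#' over ribitol peak area) per condition. These serve as the default
#' targets of [simulatePeakTable()].
#'
#' @return data.frame with columns `analyte`, `control`, `NaCl`, `sucrose`.
#' @examples
#' metaboliteTargetMeans()
#' @export
metaboliteTargetMeans <- function() {
  data.frame(
    analyte = c("Glucose", "L-glutamate", "L-phenylalanine",
                "L-isoleucine", "L-leucine", "L-proline"),
    control = c(11.85, 17.12, 0.06, 0.20, 0.38, 0.20),
    NaCl =    c(53.15, 78.54, 0.14, 0.21, 0.64, 0.36),
    sucrose = c(64.55, 57.92, 0.15, 0.59, 0.86, 0.48),
    stringsAsFactors = FALSE
  )
}

#' Simulate a GC-MS peak-area table with internal standards
#'
#' For each analyte and condition, analyte peak areas are constructed so
#' that the expected area ratio to the ribitol internal standard equals the
#' target mean, with multiplicative lognormal noise of unit mean at
#' coefficient of variation `peakCv`. Ribitol (20 nmol), norvaline
#' (20 nmol) and camphorsulfonic acid (2.5 nmol) areas are carried per
#' sample; only ribitol enters the normalization downstream.
#'
#' @param config a [SimulationConfig].
#' @param targetMeans data.frame (`analyte`, `control`, `NaCl`, `sucrose`)
#'   of strictly positive target area ratios; defaults to
#'   [metaboliteTargetMeans()].
#' @return data.frame with one row per sample x analyte: `sample_id`,
#'   `condition`, `replicate`, `analyte`, `analyte_area`, `ribitol_area`,
#'   `norvaline_area`, `camphorsulfonic_area`.
#' @examples
#' pk <- simulatePeakTable(SimulationConfig(seed = 1, peakCv = 0))
#' head(pk)
#' @export
simulatePeakTable <- function(config = SimulationConfig(),
                              targetMeans = metaboliteTargetMeans()) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  need <- c("analyte", "control", "NaCl", "sucrose")
  if (!all(need %in% names(targetMeans)))
    stop("targetMeans must have columns analyte, control, NaCl, sucrose")
  if (any(as.matrix(targetMeans[, c("control", "NaCl", "sucrose")]) <= 0))
    stop("target means must be positive")
  .withSeed(config@seed, 404L, {
    ribitol <- 20000
    conditions <- c("control", "NaCl", "sucrose")
    rows <- list()
    for (cond in conditions) {
      for (r in seq_len(config@nReplicates)) {
        mu <- targetMeans[[cond]]
        area <- mu * ribitol * .lognoise(nrow(targetMeans), config@peakCv)
        rows[[paste(cond, r)]] <- data.frame(
          sample_id = sprintf("%s_r%d", cond, r),
          condition = cond, replicate = r,
          analyte = targetMeans$analyte,
          analyte_area = area,
          ribitol_area = ribitol,
          norvaline_area = 20000,
          camphorsulfonic_area = 2500,
          stringsAsFactors = FALSE
        )
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

.MAIN_ROLES <- list(
  "Amino acid biosynthesis" = c("Glutamate family", "Aromatic amino acid family",
                                "Pyruvate family"),
  "Energy metabolism" = c("Glycolysis/gluconeogenesis", "TCA cycle",
                          "Electron transport"),
  "Transport and binding proteins" = c("Carbohydrates", "Cations and iron",
                                       "Amino acids and amines"),
  "Protein synthesis" = c("Ribosomal proteins", "Translation factors"),
  "Protein fate" = c("Degradation", "Folding and stabilization"),
  "Regulatory functions" = c("DNA interactions", "Small molecule interactions"),
  "Cellular processes" = c("Adaptations to atypical conditions",
                           "Detoxification"),
  "Cell envelope" = c("Biosynthesis of murein", "Surface structures"),
  "Hypothetical proteins" = c("Conserved", "Domain")
)

#' Simulate a functional annotation with operon structure
#'
#' Walks the genome in order, grouping consecutive genes into operons of
#' size 1-5 and assigning each operon one (main role, sub-role) pair from a
#' two-level functional category catalogue, so genes of an operon share a
#' functional class. Gene ids match [simulateProbeTable()] for the same
#' configuration.
#'
#' @param config a [SimulationConfig].
#' @return data.frame `gene_id`, `main_role`, `sub_role`, `operon_id`,
#'   `genome_order_index`.
#' @examples
#' head(simulateAnnotation(SimulationConfig(seed = 1, nGenes = 20)))
#' @export
simulateAnnotation <- function(config = SimulationConfig()) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  .withSeed(config@seed, 505L, {
    n <- config@nGenes
    genes <- sprintf("gene_%04d", seq_len(n))
    mainRole <- character(n); subRole <- character(n); operon <- character(n)
    i <- 1L; op <- 0L
    while (i <= n) {
      op <- op + 1L
      size <- min(sample(1:5, 1L, prob = c(0.45, 0.25, 0.15, 0.1, 0.05)),
                  n - i + 1L)
      mr <- sample(names(.MAIN_ROLES), 1L)
      sr <- sample(.MAIN_ROLES[[mr]], 1L)
      idx <- i:(i + size - 1L)
      mainRole[idx] <- mr
      subRole[idx] <- sr
      operon[idx] <- sprintf("operon_%04d", op)
      i <- i + size
    }
    data.frame(
      gene_id = genes, main_role = mainRole, sub_role = subRole,
      operon_id = operon, genome_order_index = seq_len(n),
      stringsAsFactors = FALSE
    )
  })
}
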