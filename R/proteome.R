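# 2D-gel spot statistics: normalization to total gel quantity, the
# low-abundance filter, standardization, per-spot one-way ANOVA across
# control/NaCl/sucrose, two-fold calls, RSD quality control and the
# peptide-mass-fingerprint acceptance rule.

#' Normalize spot volumes to total gel quantity
#'
#' Expresses every spot volume as a percentage of the summed raw volume of
#' its gel, so each gel's normalized volumes sum to exactly 100.
#'
#' @param spots data.frame `gel_id`, `condition`, `replicate`, `spot_id`,
#'   `raw_volume`.
#' @return `spots` with an added `normalized_volume` column (percent).
#' @examples
#' normalizeSpots(data.frame(gel_id = "g", condition = "control",
#'   replicate = 1, spot_id = c("a", "b", "c"), raw_volume = c(1, 1, 2)))
#' @export
normalizeSpots <- function(spots) {
  need <- c("gel_id", "spot_id", "raw_volume")
  if (!all(need %in% names(spots)))
    stop("spots need columns ", paste(need, collapse = ", "))
  if (any(spots$raw_volume < 0)) stop("raw volumes must be non-negative")
  totals <- tapply(spots$raw_volume, spots$gel_id, sum)
  if (any(totals == 0))
    stop("gel with zero total volume: ",
         paste(names(totals)[totals == 0], collapse = ", "))
  spots$normalized_volume <-
    100 * spots$raw_volume / as.vector(totals[spots$gel_id])
  spots
}

#' Flag spots below the low-abundance cut-off on every image
#'
#' A spot is eliminated only when its normalized volume is strictly below
#' `minVolume` percent on all gels; a single gel at or above the cut-off
#' retains it.
#'
#' @param normalized output of [normalizeSpots()].
#' @param minVolume percent cut-off (default 0.02).
#' @return character vector of eliminated spot ids.
#' @export
lowAbundanceFilter <- function(normalized, minVolume = 0.02) {
  if (!"normalized_volume" %in% names(normalized))
    stop("run normalizeSpots() first")
  mx <- tapply(normalized$normalized_volume, normalized$spot_id, max)
  names(mx)[mx < minVolume]
}

#' Mean-center and scale to unit standard deviation
#'
#' @param x numeric vector of at least two values.
#' @return list with `values` (standardized vector, mean 0 and sample sd
#'   1) and `degenerate` (TRUE with `values = NA` when the spread is zero).
#' @examples
#' standardizeValues(c(1, 2, 3))
#' @export
standardizeValues <- function(x) {
  if (length(x) < 2L) stop("need at least two values")
  s <- sd(x)
  if (s == 0) return(list(values = rep(NA_real_, length(x)),
                          degenerate = TRUE))
  list(values = (x - mean(x)) / s, degenerate = FALSE)
}

#' One-way ANOVA of one spot across conditions
#'
#' Classic fixed-effects one-way ANOVA (`F = MS_between / MS_within`, p
#' from the F distribution with k-1 and N-k degrees of freedom) over the
#' condition groups of one spot, both stress types entering one analysis
#' alongside the control.
#'
#' @param values numeric spot volumes.
#' @param conditions condition label per value.
#' @param alpha significance level (default 0.1).
#' @return list `F`, `p`, `significant`, `skipped`, `reason`. Spots with
#'   fewer than two groups or fewer than two replicates in any group are
#'   skipped with a reason.
#' @examples
#' anovaPerSpot(c(1, 2, 5, 6, 9, 10),
#'              rep(c("control", "NaCl", "sucrose"), each = 2))
#' @export
anovaPerSpot <- function(values, conditions, alpha = 0.1) {
  skip <- function(reason) list(F = NA_real_, p = NA_real_,
                                significant = NA, skipped = TRUE,
                                reason = reason)
  g <- factor(conditions)
  if (nlevels(g) < 2L) return(skip("fewer than two condition groups"))
  if (any(table(g) < 2L)) return(skip("a group has fewer than two replicates"))
  if (all(tapply(values, g, sd) == 0)) {
    # no within-group variance: F undefined unless means also equal
    if (sd(tapply(values, g, mean)) == 0)
      return(skip("zero variance within and between groups"))
    return(list(F = Inf, p = 0, significant = TRUE, skipped = FALSE,
                reason = NA_character_))
  }
  ht <- oneway.test(values ~ g, var.equal = TRUE)
  list(F = unname(ht$statistic), p = unname(ht$p.value),
       significant = unname(ht$p.value) < alpha, skipped = FALSE,
       reason = NA_character_)
}

#' Fold change of a stress condition versus control
#'
#' @param meanStress,meanControl condition means of normalized volumes.
#' @param fold fold cut-off (default 2).
#' @return list `ratio` and `substantial` (strictly more than `fold`-fold
#'   up or down). A zero control mean leaves the ratio undefined (NA,
#'   flagged not substantial).
#' @examples
#' foldChangeCall(3, 1)
#' @export
foldChangeCall <- function(meanStress, meanControl, fold = 2) {
  if (meanControl <= 0)
    return(list(ratio = NA_real_, substantial = NA))
  ratio <- meanStress / meanControl
  list(ratio = ratio, substantial = ratio > fold || ratio < 1 / fold)
}

#' Relative standard deviation per spot and condition
#'
#' RSD = 100 x sd / mean of the normalized volumes of one spot within one
#' condition, the replicate-reproducibility metric of 2D-gel series.
#'
#' @param normalized output of [normalizeSpots()].
#' @param rsdCutoff percent cut-off of the QC summary (default 35).
#' @return list `rsd` (data.frame `spot_id`, `condition`, `rsd`) and
#'   `fractionBelowCutoff` (share of defined RSD values strictly below the
#'   cut-off). Zero-mean spots have undefined RSD and are excluded from
#'   the summary.
#' @export
rsdQC <- function(normalized, rsdCutoff = 35) {
  if (!"normalized_volume" %in% names(normalized))
    stop("run normalizeSpots() first")
  agg <- aggregate(normalized_volume ~ spot_id + condition, normalized,
                   function(v) c(m = mean(v), s = sd(v)))
  m <- agg$normalized_volume[, "m"]
  s <- agg$normalized_volume[, "s"]
  rsd <- ifelse(m > 0, 100 * s / m, NA_real_)
  df <- data.frame(spot_id = agg$spot_id, condition = agg$condition,
                   rsd = rsd, stringsAsFactors = FALSE)
  list(rsd = df,
       fractionBelowCutoff = mean(df$rsd[!is.na(df$rsd)] < rsdCutoff))
}

#' Accept, defer or reject a peptide-mass-fingerprint identification
#'
#' The acceptance rule for protein identifications: positive when at least
#' two spectra reach a Mowse score of at least 50 and the sequence
#' coverage reaches at least 30 percent; when the score criterion is met
#' but coverage falls short, the spot is deferred to tandem MS
#' (`needs_msms`); otherwise it is rejected.
#'
#' @param scores numeric vector of per-spectrum Mowse scores.
#' @param coverage sequence coverage in percent (0-100).
#' @param minScore,minHits,minCoverage rule parameters (defaults 50, 2, 30).
#' @return one of "accepted", "needs_msms", "rejected".
#' @examples
#' identificationFilter(c(55, 62), 35)
#' identificationFilter(c(55, 62), 20)
#' identificationFilter(80, 90)
#' @export
identificationFilter <- function(scores, coverage, minScore = 50,
                                 minHits = 2, minCoverage = 30) {
  if (length(scores) == 0L) stop("at least one spectrum score is required")
  if (coverage < 0 || coverage > 100) stop("coverage must lie in [0, 100]")
  scoresOk <- sum(scores >= minScore) >= minHits
  if (scoresOk && coverage >= minCoverage) return("accepted")
  if (scoresOk) return("needs_msms")
  "rejected"
}

#' Full spot-table statistics pipeline
#'
#' Normalizes a matched spot table to total gel quantity, eliminates spots
#' below the low-abundance cut-off on every image, and computes per
#' retained spot the one-way ANOVA across conditions, fold changes of each
#' stress versus control with the two-fold substantial flag, and
#' per-condition RSD values.
#'
#' @param spots data.frame `gel_id`, `condition`, `replicate`, `spot_id`,
#'   `raw_volume`; conditions must include "control".
#' @param alpha ANOVA significance level (default 0.1).
#' @param fold fold-change cut-off (default 2).
#' @param minVolume low-abundance cut-off in percent (default 0.02).
#' @param rsdCutoff RSD QC cut-off in percent (default 35).
#' @return list with `stats` (per-spot data.frame: condition means, `F`,
#'   `p`, `significant`, per-stress `ratio_*` and `substantial_*`,
#'   per-condition `rsd_*`), `eliminated` (low-abundance spot ids),
#'   `normalized` (the normalized table) and `qc` (the [rsdQC()] summary).
#' @examples
#' sim <- simulateSpotTable(SimulationConfig(seed = 1, nSpots = 40,
#'   nPlantedSpots = 4))
#' res <- spotStats(sim$spots)
#' head(res$stats)
#' @export
spotStats <- function(spots, alpha = 0.1, fold = 2, minVolume = 0.02,
                      rsdCutoff = 35) {
  norm <- normalizeSpots(spots)
  eliminated <- lowAbundanceFilter(norm, minVolume)
  kept <- norm[!norm$spot_id %in% eliminated, , drop = FALSE]
  conditions <- unique(kept$condition)
  if (!"control" %in% conditions) stop("a control condition is required")
  stresses <- setdiff(conditions, "control")
  qc <- rsdQC(kept, rsdCutoff)

  rows <- lapply(split(kept, kept$spot_id), function(sub) {
    av <- anovaPerSpot(sub$normalized_volume, sub$condition, alpha)
    means <- tapply(sub$normalized_volume, sub$condition, mean)
    row <- data.frame(spot_id = sub$spot_id[1], stringsAsFactors = FALSE)
    for (cond in conditions) row[[paste0("mean_", cond)]] <- means[[cond]]
    row$F <- av$F; row$p <- av$p; row$significant <- av$significant
    for (st in stresses) {
      fc <- foldChangeCall(means[[st]], means[["control"]], fold)
      row[[paste0("ratio_", st)]] <- fc$ratio
      row[[paste0("substantial_", st)]] <- fc$substantial
    }
    rsd <- qc$rsd[qc$rsd$spot_id == sub$spot_id[1], ]
    for (cond in conditions)
      row[[paste0("rsd_", cond)]] <- rsd$rsd[rsd$condition == cond]
    row
  })
  stats <- do.call(rbind, rows)
  stats <- stats[order(stats$spot_id), , drop = FALSE]
  rownames(stats) <- NULL
  list(stats = stats, eliminated = eliminated, normalized = norm, qc = qc)
}
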