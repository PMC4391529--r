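# GC-MS relative quantification against the ribitol internal standard and
# per-metabolite two-sample t-tests of each stress condition vs control.

#' Internal-standard relative quantification
#'
#' Divides the analyte peak area by the ribitol internal-standard peak
#' area of the same sample; the other spiked standards (norvaline,
#' camphorsulfonic acid) are carried only as QC columns and never enter
#' the normalization.
#'
#' @param analyteArea,ribitolArea numeric vectors (recycled).
#' @return numeric vector of dimensionless area ratios.
#' @examples
#' relativeQuant(237, 20)
#' @export
relativeQuant <- function(analyteArea, ribitolArea) {
  if (any(ribitolArea <= 0))
    stop("ribitol area must be positive; sample invalid")
  if (any(analyteArea < 0)) stop("analyte areas must be non-negative")
  analyteArea / ribitolArea
}

#' Two-sample Student's t-test of stress versus control
#'
#' Two-sided pooled-variance t-test (p from the t distribution with
#' n1+n2-2 degrees of freedom); a Welch variant is available behind
#' `welch = TRUE` but is not the default. Degenerate zero-variance inputs
#' are resolved by the means: equal means give p = 1, unequal means p = 0.
#'
#' @param stress,control numeric vectors with at least two values each.
#' @param welch use the unequal-variance (Welch) test instead.
#' @return list `t`, `df`, `p`.
#' @examples
#' ttestVsControl(c(4, 5, 6), c(1, 2, 3))
#' @export
ttestVsControl <- function(stress, control, welch = FALSE) {
  if (length(stress) < 2L || length(control) < 2L)
    stop("both groups need at least two values")
  if (sd(stress) == 0 && sd(control) == 0) {
    df <- length(stress) + length(control) - 2
    if (mean(stress) == mean(control))
      return(list(t = 0, df = df, p = 1))
    return(list(t = Inf, df = df, p = 0))
  }
  ht <- t.test(stress, control, var.equal = !welch)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Per-metabolite condition means and significance table
#'
#' Computes, per analyte, the mean ribitol-normalized relative quantity of
#' every condition and the t-test p values of each stress versus control,
#' with strict p < `alpha` significance flags. Rows are sorted by analyte
#' name (C locale), so the output is invariant to permutations of the
#' input rows.
#'
#' @param peaks data.frame `sample_id`, `condition`, `replicate`,
#'   `analyte`, `analyte_area`, `ribitol_area` (e.g. from
#'   [simulatePeakTable()]).
#' @param alpha significance level (default 0.05).
#' @param welch passed to [ttestVsControl()].
#' @return data.frame, one row per analyte: `analyte`, `mean_control`,
#'   `mean_NaCl`, `mean_sucrose`, `p_NaCl`, `p_sucrose`, `sig_NaCl`,
#'   `sig_sucrose`. Analytes missing a condition are skipped with a
#'   warning; an empty input gives a zero-row table.
#' @examples
#' pk <- simulatePeakTable(SimulationConfig(seed = 1, peakCv = 0))
#' buildMetaboliteTable(pk)
#' @export
buildMetaboliteTable <- function(peaks, alpha = 0.05, welch = FALSE) {
  need <- c("condition", "analyte", "analyte_area", "ribitol_area")
  if (!all(need %in% names(peaks)))
    stop("peaks need columns ", paste(need, collapse = ", "))
  conditions <- c("control", "NaCl", "sucrose")
  empty <- data.frame(analyte = character(),
                      mean_control = numeric(), mean_NaCl = numeric(),
                      mean_sucrose = numeric(), p_NaCl = numeric(),
                      p_sucrose = numeric(), sig_NaCl = logical(),
                      sig_sucrose = logical(), stringsAsFactors = FALSE)
  if (nrow(peaks) == 0L) return(empty)
  peaks$ratio <- relativeQuant(peaks$analyte_area, peaks$ribitol_area)
  analytes <- unique(peaks$analyte)
  rows <- list()
  for (a in analytes) {
    sub <- peaks[peaks$analyte == a, , drop = FALSE]
    have <- conditions %in% sub$condition
    if (!all(have)) {
      warning("analyte '", a, "' lacks condition(s) ",
              paste(conditions[!have], collapse = ", "), "; skipped")
      next
    }
    byCond <- split(sub$ratio, factor(sub$condition, levels = conditions))
    tN <- ttestVsControl(byCond$NaCl, byCond$control, welch)
    tS <- ttestVsControl(byCond$sucrose, byCond$control, welch)
    rows[[a]] <- data.frame(
      analyte = a,
      mean_control = mean(byCond$control),
      mean_NaCl = mean(byCond$NaCl),
      mean_sucrose = mean(byCond$sucrose),
      p_NaCl = tN$p, p_sucrose = tS$p,
      sig_NaCl = tN$p < alpha, sig_sucrose = tS$p < alpha,
      stringsAsFactors = FALSE
    )
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$analyte, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}
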