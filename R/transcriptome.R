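# Probe-level differential expression: positional probe filter, per-gene
# replicate means, the all-replicates fold-change rule, the sucrose/NaCl
# grouping and per-category summaries.

#' Keep probes downstream of the translational start
#'
#' Retains exactly the probes whose midpoint offset is at or beyond +1
#' (the first base of the start codon); upstream probes (negative offsets)
#' are dropped. Row order is preserved.
#'
#' @param probes data.frame with at least an `offset` column (bp relative
#'   to the translational start at +1; negative = upstream).
#' @return the retained rows of `probes`.
#' @examples
#' filterProbes(data.frame(offset = c(-120, -5, 10, 150)))
#' @export
filterProbes <- function(probes) {
  if (!"offset" %in% names(probes)) stop("probes need an offset column")
  probes[probes$offset >= 1L, , drop = FALSE]
}

#' Average probe log2 ratios of one gene
#'
#' Arithmetic mean of the probe-level log2 ratios per replicate, after
#' positional filtering.
#'
#' @param probes data.frame of probes of one gene and contrast, with
#'   replicate columns.
#' @param replicateCols names of the replicate columns; defaults to every
#'   column matching `^rep`.
#' @return named numeric vector of per-replicate means, or NULL when no
#'   probe remains (the gene is then not evaluated).
#' @examples
#' geneRatio(data.frame(rep1 = c(2, 0), rep2 = c(1, 1)))
#' @export
geneRatio <- function(probes,
                      replicateCols = grep("^rep", names(probes),
                                           value = TRUE)) {
  if (nrow(probes) == 0L) return(NULL)
  colMeans(probes[, replicateCols, drop = FALSE])
}

.deStatus <- function(means, threshold, requireAll, nReplicates) {
  if (is.null(means) || length(means) == 0L) return("not_evaluated")
  if (anyNA(means) || length(means) < nReplicates) return("not_evaluated")
  need <- if (requireAll) length(means) else floor(length(means) / 2) + 1
  if (sum(means > threshold) >= need) return("up")
  if (sum(means < -threshold) >= need) return("down")
  "unchanged"
}

#' Call differential expression from a probe-level ratio table
#'
#' Applies the full probe-to-gene rule: drop probes upstream of the
#' translational start, average remaining probe log2 ratios per gene and
#' replicate, then call `up` when every replicate mean strictly exceeds
#' `+threshold`, `down` when every replicate mean falls strictly below
#' `-threshold`, `unchanged` otherwise, and `not_evaluated` when no probe
#' passes the positional filter.
#'
#' @param probes data.frame (`probe_id`, `gene_id`, `offset`, `contrast`,
#'   `rep1..repK`); the `contrast` column is optional (a single contrast is
#'   assumed when missing).
#' @param config a [DEConfig-class].
#' @return data.frame, one row per gene x contrast: `gene_id`, `contrast`,
#'   replicate mean columns, `n_probes` (probes passing the filter) and
#'   `status`.
#' @examples
#' probes <- data.frame(probe_id = c("p1", "p2"), gene_id = "g1",
#'   offset = c(10, 50), contrast = "NaCl_vs_control",
#'   rep1 = c(1.5, 1.7), rep2 = c(1.4, 1.2), rep3 = c(1.8, 1.3))
#' callDE(probes)
#' @export
callDE <- function(probes, config = DEConfig()) {
  stopifnot(is(config, "DEConfig"))
  need <- c("gene_id", "offset")
  if (!all(need %in% names(probes)))
    stop("probes need columns ", paste(need, collapse = ", "))
  if (!"contrast" %in% names(probes)) probes$contrast <- "stress_vs_control"
  repCols <- grep("^rep", names(probes), value = TRUE)
  if (length(repCols) == 0L) stop("no replicate columns (rep1, rep2, ...)")

  genes <- unique(probes$gene_id)
  contrasts <- unique(probes$contrast)
  kept <- filterProbes(probes)
  out <- vector("list", length(genes) * length(contrasts))
  k <- 0L
  for (ct in contrasts) {
    keptCt <- kept[kept$contrast == ct, , drop = FALSE]
    byGene <- split(keptCt, factor(keptCt$gene_id, levels = genes))
    for (g in genes) {
      k <- k + 1L
      sub <- byGene[[g]]
      means <- geneRatio(sub, repCols)
      row <- data.frame(gene_id = g, contrast = ct,
                        stringsAsFactors = FALSE)
      if (is.null(means)) {
        for (rc in repCols) row[[rc]] <- NA_real_
        row$n_probes <- 0L
      } else {
        for (rc in repCols) row[[rc]] <- means[[rc]]
        row$n_probes <- nrow(sub)
      }
      row$status <- .deStatus(means, config@threshold, config@requireAll,
                              config@nReplicates)
      out[[k]] <- row
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Group genes by their sucrose/NaCl response pattern
#'
#' Classifies each gene from its three contrast calls (NaCl vs control,
#' sucrose vs control, and the direct sucrose vs NaCl comparison) into one
#' response group:
#' * G1 - higher in the direct comparison under sucrose, or up-regulated
#'   only under sucrose stress;
#' * G2 - down-regulated only under sucrose stress;
#' * G3 - higher in the direct comparison under NaCl, or up-regulated only
#'   under NaCl stress;
#' * G4 - down-regulated only under NaCl stress;
#' * none - any other pattern.
#' The direct-contrast route takes precedence over the single-condition
#' routes, and groups are assigned in the order G1..G4, so every gene
#' lands in at most one group.
#'
#' @param calls output of [callDE()] covering the contrasts
#'   `NaCl_vs_control`, `sucrose_vs_control` and `sucrose_vs_NaCl`.
#' @return data.frame `gene_id`, `group` (G1/G2/G3/G4/none).
#' @export
assignGroups <- function(calls) {
  need <- c("NaCl_vs_control", "sucrose_vs_control", "sucrose_vs_NaCl")
  if (!all(need %in% calls$contrast))
    stop("calls must cover contrasts ", paste(need, collapse = ", "))
  wide <- lapply(need, function(ct) {
    x <- calls[calls$contrast == ct, c("gene_id", "status")]
    setNames(x$status, x$gene_id)
  })
  names(wide) <- c("nacl", "suc", "direct")
  genes <- unique(calls$gene_id)
  grp <- vapply(genes, function(g) {
    nacl <- wide$nacl[[g]]; suc <- wide$suc[[g]]; direct <- wide$direct[[g]]
    if (identical(direct, "up")) return("G1")
    if (identical(direct, "down")) return("G3")
    if (identical(suc, "up") && !identical(nacl, "up")) return("G1")
    if (identical(suc, "down") && !identical(nacl, "down")) return("G2")
    if (identical(nacl, "up") && !identical(suc, "up")) return("G3")
    if (identical(nacl, "down") && !identical(suc, "down")) return("G4")
    "none"
  }, character(1))
  data.frame(gene_id = genes, group = unname(grp), stringsAsFactors = FALSE)
}

#' Count regulated genes per functional category
#'
#' Tabulates up- and down-regulated genes per main functional role and
#' contrast. Genes missing from the annotation are counted under the role
#' "unknown".
#'
#' @param calls output of [callDE()].
#' @param annotation data.frame with `gene_id` and `main_role`.
#' @return data.frame `contrast`, `main_role`, `up`, `down`; one row per
#'   (contrast, role) with at least one called gene, plus all-zero roles
#'   dropped. An empty call set gives a zero-row table.
#' @export
categorySummary <- function(calls, annotation) {
  if (!all(c("gene_id", "main_role") %in% names(annotation)))
    stop("annotation needs gene_id and main_role")
  de <- calls[calls$status %in% c("up", "down"), , drop = FALSE]
  role <- annotation$main_role[match(de$gene_id, annotation$gene_id)]
  role[is.na(role)] <- "unknown"
  if (nrow(de) == 0L)
    return(data.frame(contrast = character(), main_role = character(),
                      up = integer(), down = integer(),
                      stringsAsFactors = FALSE))
  tab <- table(contrast = de$contrast, main_role = role, status = de$status)
  grid <- expand.grid(contrast = dimnames(tab)$contrast,
                      main_role = dimnames(tab)$main_role,
                      stringsAsFactors = FALSE)
  grid$up <- mapply(function(ct, mr)
    if ("up" %in% dimnames(tab)$status) tab[ct, mr, "up"] else 0L,
    grid$contrast, grid$main_role)
  grid$down <- mapply(function(ct, mr)
    if ("down" %in% dimnames(tab)$status) tab[ct, mr, "down"] else 0L,
    grid$contrast, grid$main_role)
  grid <- grid[grid$up + grid$down > 0, , drop = FALSE]
  grid <- grid[order(grid$contrast, grid$main_role), , drop = FALSE]
  rownames(grid) <- NULL
  grid
}
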