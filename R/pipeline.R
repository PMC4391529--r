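# One-config end-to-end run: generate all synthetic inputs, then run the
# ortholog screen, the DE caller, the spot statistics, the metabolite
# table and the treemap from them, writing plain-text tables and SVGs.

#' Read a simulation configuration from YAML or JSON-like YAML
#'
#' Accepts a flat mapping whose keys match the arguments of
#' [SimulationConfig()] (e.g. `seed`, `nGenes`, `probeNoiseSd`); unknown
#' keys are rejected so typos do not silently fall back to defaults.
#'
#' @param file path to a YAML file.
#' @return a [SimulationConfig-class].
#' @export
readSimulationConfig <- function(file) {
  vals <- yaml::read_yaml(file)
  known <- names(formals(SimulationConfig))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown configuration keys: ", paste(bad, collapse = ", "))
  do.call(SimulationConfig, vals)
}

#' Write every synthetic input of one configuration
#'
#' Materializes the generator outputs as the plain-text formats the
#' analysis stages read: multi-FASTA proteomes, tab-separated probe, spot
#' and peak tables, an annotation table and JSON-like truth tables (TSV).
#'
#' @param config a [SimulationConfig-class].
#' @param dir output directory (created if needed).
#' @return named list of the generated objects, invisibly writing
#'   `source_proteome.fasta`, `target_proteome.fasta`,
#'   `ortholog_truth.tsv`, `probe_table.tsv`, `probe_truth.tsv`,
#'   `spot_table.tsv`, `spot_truth.tsv`, `peak_table.tsv` and
#'   `annotation.tsv` under `dir`.
#' @export
simulateAll <- function(config = SimulationConfig(), dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gp <- simulateGenomePair(config)
  pt <- simulateProbeTable(config)
  st <- simulateSpotTable(config)
  pk <- simulatePeakTable(config)
  ann <- simulateAnnotation(config)
  Biostrings::writeXStringSet(gp$source,
                              file.path(dir, "source_proteome.fasta"))
  Biostrings::writeXStringSet(gp$target,
                              file.path(dir, "target_proteome.fasta"))
  writeTsv(gp$truth, file.path(dir, "ortholog_truth.tsv"))
  writeTsv(pt$probes, file.path(dir, "probe_table.tsv"))
  writeTsv(pt$truth, file.path(dir, "probe_truth.tsv"))
  writeTsv(st$spots, file.path(dir, "spot_table.tsv"))
  writeTsv(st$truth, file.path(dir, "spot_truth.tsv"))
  writeTsv(pk, file.path(dir, "peak_table.tsv"))
  writeTsv(ann, file.path(dir, "annotation.tsv"))
  invisible(list(genomePair = gp, probeTable = pt, spotTable = st,
                 peakTable = pk, annotation = ann))
}

#' Run the whole analysis from one configuration
#'
#' Generates every synthetic input, then runs all five analysis stages:
#' the reciprocal best-hit presence matrix of the planted genome pair
#' (with its identity heatmap), the differential-expression calls with
#' sucrose/NaCl response groups and per-category counts, the 2D-gel spot
#' statistics with QC, the ribitol-normalized metabolite table, and the
#' genome-ordered treemap. The treemap overlay takes each gene's mRNA
#' log2 from the mean NaCl-vs-control replicate ratio and, as a
#' demonstration linkage, maps spot `k` of the gel table onto the gene
#' with genome order index `k` for the protein layer.
#'
#' @param config a [SimulationConfig-class].
#' @param outDir output directory.
#' @param screenConfig a [ScreenConfig-class].
#' @param deConfig a [DEConfig-class].
#' @param alpha,fold,minVolume spot-statistics parameters.
#' @param spec a [colorSpec()] for the treemap.
#' @return named list with every intermediate result; files are written
#'   under `outDir` (`presence_matrix.tsv`, `presence_heatmap.svg`,
#'   `de_calls.tsv`, `de_groups.tsv`, `category_summary.tsv`,
#'   `spot_stats.tsv`, `spot_qc.tsv`, `metabolite_table.tsv`,
#'   `treemap.svg` plus the simulated inputs).
#' @examples
#' \donttest{
#' cfg <- SimulationConfig(seed = 1, nGenes = 40, nSpots = 50,
#'   nPlantedSpots = 5, orthologIdentityLevels = c(0.6, 0.9), decoyCount = 3)
#' res <- runPipeline(cfg, tempfile("run"))
#' names(res)
#' }
#' @export
runPipeline <- function(config = SimulationConfig(), outDir,
                        screenConfig = ScreenConfig(),
                        deConfig = DEConfig(),
                        alpha = 0.1, fold = 2, minVolume = 0.02,
                        spec = colorSpec()) {
  inputs <- simulateAll(config, outDir)

  # ortholog screen on the planted genome pair
  seeds <- data.frame(seed_id = inputs$genomePair$truth$seed_id,
                      organism = "SRC", stringsAsFactors = FALSE)
  pm <- buildPresenceMatrix(
    seeds,
    proteomes = list(SRC = inputs$genomePair$source,
                     TGT = inputs$genomePair$target),
    config = screenConfig
  )
  writePresenceMatrix(pm, file.path(outDir, "presence_matrix.tsv"))
  renderPresenceHeatmap(pm, file.path(outDir, "presence_heatmap.svg"))

  # transcriptome
  calls <- callDE(inputs$probeTable$probes, deConfig)
  groups <- assignGroups(calls)
  summary <- categorySummary(calls, inputs$annotation)
  writeTsv(calls, file.path(outDir, "de_calls.tsv"))
  writeTsv(groups, file.path(outDir, "de_groups.tsv"))
  writeTsv(summary, file.path(outDir, "category_summary.tsv"))

  # proteome
  spots <- spotStats(inputs$spotTable$spots, alpha = alpha, fold = fold,
                     minVolume = minVolume)
  writeTsv(spots$stats, file.path(outDir, "spot_stats.tsv"))
  writeTsv(spots$qc$rsd, file.path(outDir, "spot_qc.tsv"))

  # metabolome
  metab <- buildMetaboliteTable(inputs$peakTable)
  writeTsv(metab, file.path(outDir, "metabolite_table.tsv"))

  # treemap overlay: mRNA from the NaCl contrast, protein from spot k ->
  # gene with genome order index k (demonstration linkage)
  nacl <- calls[calls$contrast == "NaCl_vs_control", , drop = FALSE]
  repCols <- grep("^rep", names(nacl), value = TRUE)
  mrna <- rowMeans(nacl[, repCols, drop = FALSE])
  overlay <- data.frame(gene_id = nacl$gene_id, mrna_log2 = mrna,
                        protein_log2 = NA_real_, stringsAsFactors = FALSE)
  spotIdx <- match(sprintf("spot_%04d",
                           inputs$annotation$genome_order_index),
                   spots$stats$spot_id)
  gi <- match(inputs$annotation$gene_id, overlay$gene_id)
  overlay$protein_log2[gi[!is.na(spotIdx)]] <-
    log2(spots$stats$ratio_NaCl[spotIdx[!is.na(spotIdx)]])
  tree <- buildHierarchy(inputs$annotation)
  layout <- layoutTreemap(tree, c(0, 0, 1200, 800))
  renderTreemap(layout, overlay, file.path(outDir, "treemap.svg"), spec)

  invisible(list(inputs = inputs, presence = pm, calls = calls,
                 groups = groups, categorySummary = summary,
                 spotStats = spots, metabolites = metab,
                 layout = layout, overlay = overlay, outDir = outDir))
}
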