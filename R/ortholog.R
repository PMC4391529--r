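# Reciprocal best-hit screen: a seed gene is called present in a target
# organism when its best hit there, searched back against the source
# proteome, returns the seed itself.

#' Reciprocal best-hit presence call for one seed gene
#'
#' Forward search: best hit of the seed in the target proteome under the
#' score and overlap thresholds. Back search: best hit of that target
#' sequence in the source proteome. The seed is `present` only when the
#' back search returns exactly the seed id - a duplicated paralog that
#' captures the back search therefore yields `absent`. The reported
#' identity comes from the forward alignment.
#'
#' @param seedId id of the seed gene; must name a sequence of
#'   `sourceProteome`.
#' @param sourceProteome,targetProteome named [Biostrings::AAStringSet]s.
#' @param config a [ScreenConfig].
#' @return one-row data.frame: `seed_id`, `status` ("present"/"absent"),
#'   `identity` (NA when absent), `hit_id` (target id of the forward hit,
#'   NA when there is none).
#' @examples
#' src <- Biostrings::AAStringSet(c(g1 = strrep("MKTAYIAKQR", 10)))
#' reciprocalBestHit("g1", src, src, ScreenConfig())
#' @export
reciprocalBestHit <- function(seedId, sourceProteome, targetProteome,
                              config = ScreenConfig()) {
  stopifnot(is(config, "ScreenConfig"))
  if (!seedId %in% names(sourceProteome))
    stop("seed '", seedId, "' is not part of the source proteome")
  absent <- data.frame(seed_id = seedId, status = "absent",
                       identity = NA_real_, hit_id = NA_character_,
                       stringsAsFactors = FALSE)
  fwd <- bestHit(as.character(sourceProteome[[seedId]]), targetProteome,
                 config)
  if (is.null(fwd)) return(absent)
  back <- bestHit(as.character(targetProteome[[fwd@subjectId]]),
                  sourceProteome, config)
  if (is.null(back) || back@subjectId != seedId) {
    absent$hit_id <- fwd@subjectId
    return(absent)
  }
  data.frame(seed_id = seedId, status = "present",
             identity = fwd@identity, hit_id = fwd@subjectId,
             stringsAsFactors = FALSE)
}

#' Presence/identity matrix of a seed panel across organisms
#'
#' Runs the reciprocal best-hit screen for every (seed gene, organism)
#' pair and assembles the presence matrix: blue-shaded identity where a
#' reciprocal homolog exists, white (absent) where it does not.
#'
#' @param seeds data.frame with columns `seed_id` and `organism`
#'   (the source organism each seed belongs to); extra columns such as
#'   `gene_symbol` are ignored.
#' @param proteomes named list of [Biostrings::AAStringSet], one per
#'   organism; must cover every seed's source organism and every target
#'   organism.
#' @param config a [ScreenConfig].
#' @param organisms organism codes to screen (columns); defaults to all
#'   names of `proteomes`.
#' @return a [PresenceMatrix-class].
#' @examples
#' prot <- Biostrings::AAStringSet(c(g1 = strrep("MKTAYIAKQRQISFVK", 15)))
#' seeds <- data.frame(seed_id = "g1", organism = "Eco")
#' buildPresenceMatrix(seeds, list(Eco = prot))
#' @export
buildPresenceMatrix <- function(seeds, proteomes, config = ScreenConfig(),
                                organisms = names(proteomes)) {
  stopifnot(is(config, "ScreenConfig"))
  if (nrow(seeds) == 0L) stop("seed panel must be non-empty")
  if (!all(c("seed_id", "organism") %in% names(seeds)))
    stop("seeds needs columns seed_id and organism")
  if (is.null(names(proteomes)) || any(names(proteomes) == ""))
    stop("proteomes must be a named list")
  empty <- vapply(proteomes, length, integer(1)) == 0L
  if (any(empty))
    stop("organism with empty proteome: ",
         paste(names(proteomes)[empty], collapse = ", "))
  missing <- setdiff(unique(c(seeds$organism, organisms)), names(proteomes))
  if (length(missing))
    stop("no proteome for organism: ", paste(missing, collapse = ", "))

  nS <- nrow(seeds); nO <- length(organisms)
  status <- matrix("absent", nS, nO,
                   dimnames = list(seeds$seed_id, organisms))
  ident <- matrix(NA_real_, nS, nO,
                  dimnames = list(seeds$seed_id, organisms))
  hits <- matrix(NA_character_, nS, nO,
                 dimnames = list(seeds$seed_id, organisms))
  for (j in seq_len(nO)) {
    tgt <- proteomes[[organisms[j]]]
    for (i in seq_len(nS)) {
      src <- proteomes[[seeds$organism[i]]]
      call <- reciprocalBestHit(seeds$seed_id[i], src, tgt, config)
      status[i, j] <- call$status
      ident[i, j] <- call$identity
      hits[i, j] <- call$hit_id
    }
  }
  new("PresenceMatrix", seeds = seeds$seed_id, organisms = organisms,
      status = status, identity = ident, hits = hits)
}

#' Write a presence matrix as TSV
#'
#' Rows are seed genes, columns organisms; cells hold the forward-alignment
#' identity, or NA where the organism has no reciprocal homolog.
#'
#' @param pm a [PresenceMatrix-class].
#' @param file output path.
#' @return the file path, invisibly.
#' @export
writePresenceMatrix <- function(pm, file) {
  stopifnot(is(pm, "PresenceMatrix"))
  df <- data.frame(seed_id = pm@seeds,
                   as.data.frame(pm@identity, check.names = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Render a presence matrix as an SVG heatmap
#'
#' One cell per (seed, organism): white where absent, blue shaded by
#' identity where present (full blue at identity 1). The SVG is plain
#' deterministic markup; cells carry `class="cell"`.
#'
#' @param pm a [PresenceMatrix-class].
#' @param file output SVG path.
#' @param cellSize cell edge length in px.
#' @return the file path, invisibly.
#' @export
renderPresenceHeatmap <- function(pm, file, cellSize = 18) {
  stopifnot(is(pm, "PresenceMatrix"))
  nS <- length(pm@seeds); nO <- length(pm@organisms)
  margin <- c(left = 110, top = 70)
  wd <- margin["left"] + nO * cellSize + 10
  ht <- margin["top"] + nS * cellSize + 10
  ramp <- grDevices::colorRamp(c("#FFFFFF", "#08519C"), space = "rgb")
  lines <- c(.svgOpen(wd, ht))
  for (j in seq_len(nO)) {
    lines <- c(lines, .svgText(margin["left"] + (j - 0.5) * cellSize,
                               margin["top"] - 6, pm@organisms[j],
                               anchor = "middle", size = 9, rotate = -45))
  }
  for (i in seq_len(nS)) {
    y <- margin["top"] + (i - 1) * cellSize
    lines <- c(lines, .svgText(margin["left"] - 6, y + cellSize * 0.7,
                               pm@seeds[i], anchor = "end", size = 9))
    for (j in seq_len(nO)) {
      fill <- if (pm@status[i, j] == "present")
        .rgbHex(ramp(pm@identity[i, j])) else "#FFFFFF"
      lines <- c(lines, .svgRect(margin["left"] + (j - 1) * cellSize, y,
                                 cellSize, cellSize, fill = fill,
                                 stroke = "#666666", class = "cell"))
    }
  }
  lines <- c(lines, .svgClose())
  writeLines(lines, file)
  invisible(file)
}

#' Load the osmolyte seed gene panel
#'
#' Reads a seed panel TSV (`seed_id`, `organism`, `gene_symbol`). With no
#' argument, loads the panel shipped with the package: the classical
#' osmoprotectant-solute genes used to probe alpha-proteobacterial
#' genomes - potassium transport (kup, trkAHG, kdpABCDEF), glutamate
#' synthesis (glnA, gltBD, gdhA), glycine betaine synthesis (betABCI) and
#' transport (betS), glycine betaine/proline/carnitine transport (proP,
#' proVWZ), proline synthesis (proABC) and trehalose synthesis (ostAB).
#'
#' @param file path to a panel TSV; defaults to the shipped panel.
#' @return data.frame `seed_id`, `organism`, `gene_symbol`.
#' @examples
#' nrow(osmolyteSeedPanel())
#' @export
osmolyteSeedPanel <- function(file = system.file("extdata",
                                                 "osmolyte_seed_panel.tsv",
                                                 package = "OsmoOmics")) {
  df <- read.delim(file, stringsAsFactors = FALSE)
  need <- c("seed_id", "organism", "gene_symbol")
  if (!all(need %in% names(df)))
    stop("seed panel needs columns ", paste(need, collapse = ", "))
  df
}
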