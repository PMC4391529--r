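# Genome-ordered hierarchical treemap: main role -> sub-role -> operon ->
# gene. Leaves are genes of weight 1; the plane is partitioned by
# alternating slice directions so sibling cells tile their parent exactly
# and consecutive operon members share an edge. Protein log2 ratios color
# the cells, mRNA log2 ratios the gene circles and operon connectors.

.node <- function(level, label, children = list(), geneId = NA_character_,
                  genomeIndex = NA_integer_) {
  w <- if (length(children)) sum(vapply(children, `[[`, numeric(1), "weight"))
       else 1
  list(level = level, label = label, weight = w, children = children,
       gene_id = geneId, genome_order_index = genomeIndex)
}

#' Build the functional-category hierarchy of a genome
#'
#' Assembles the four-level tree main role -> sub-role -> operon -> gene
#' from a functional annotation. Leaves are genes of layout weight 1 and
#' internal weights are sums over children. At every level, siblings are
#' ordered by the smallest genome order index they contain, and the genes
#' of an operon are ordered by genome position, so the layout can keep
#' genome-consecutive genes in adjacent cells.
#'
#' @param annotation data.frame `gene_id`, `main_role`, `sub_role`,
#'   `operon_id`, `genome_order_index` (unique).
#' @return the root node: a nested list with fields `level`, `label`,
#'   `weight`, `children`, and on leaves `gene_id` and
#'   `genome_order_index`.
#' @examples
#' ann <- simulateAnnotation(SimulationConfig(seed = 1, nGenes = 12))
#' tree <- buildHierarchy(ann)
#' tree$weight
#' @export
buildHierarchy <- function(annotation) {
  need <- c("gene_id", "main_role", "sub_role", "operon_id",
            "genome_order_index")
  if (!all(need %in% names(annotation)))
    stop("annotation needs columns ", paste(need, collapse = ", "))
  if (anyDuplicated(annotation$genome_order_index))
    stop("genome_order_index must be unique")
  ann <- annotation[order(annotation$genome_order_index), , drop = FALSE]

  orderedSplit <- function(df, col) {
    parts <- split(df, df[[col]])
    parts[order(vapply(parts, function(p) min(p$genome_order_index),
                       numeric(1)))]
  }
  roleNodes <- lapply(orderedSplit(ann, "main_role"), function(roleDf) {
    subNodes <- lapply(orderedSplit(roleDf, "sub_role"), function(subDf) {
      opNodes <- lapply(orderedSplit(subDf, "operon_id"), function(opDf) {
        leaves <- lapply(seq_len(nrow(opDf)), function(i)
          .node("leaf", opDf$gene_id[i], geneId = opDf$gene_id[i],
                genomeIndex = opDf$genome_order_index[i]))
        .node("operon", opDf$operon_id[1], leaves)
      })
      .node("sub_role", subDf$sub_role[1], unname(opNodes))
    })
    .node("main_role", roleDf$main_role[1], unname(subNodes))
  })
  .node("root", "genome", unname(roleNodes))
}

#' Lay out a hierarchy as a treemap
#'
#' Recursive ordered rectangular partition: each node's children tile its
#' rectangle exactly, side by side, with areas proportional to their
#' weights; the slice direction alternates with depth. Because siblings
#' are placed in order along one axis, consecutive children always share a
#' full edge - in particular genome-consecutive genes within an operon.
#'
#' @param tree root node from [buildHierarchy()].
#' @param canvas numeric `c(x, y, width, height)` of the drawing area.
#' @param minAspect optional lower bound on leaf aspect ratio
#'   (shorter/longer side); leaves below it trigger a warning, useful as a
#'   layout sanity check on pathological hierarchies.
#' @return data.frame, one row per node: `level`, `label`, `gene_id`,
#'   `genome_order_index`, `depth`, `x`, `y`, `w`, `h`.
#' @examples
#' ann <- simulateAnnotation(SimulationConfig(seed = 1, nGenes = 12))
#' layout <- layoutTreemap(buildHierarchy(ann), c(0, 0, 400, 300))
#' head(layout)
#' @export
layoutTreemap <- function(tree, canvas = c(0, 0, 1000, 700),
                          minAspect = 0) {
  if (length(canvas) != 4L || canvas[3] <= 0 || canvas[4] <= 0)
    stop("canvas must be c(x, y, width, height) with positive area")
  rows <- list()
  recurse <- function(node, x, y, w, h, depth) {
    if (node$weight <= 0) stop("zero-weight node: ", node$label)
    rows[[length(rows) + 1L]] <<- data.frame(
      level = node$level, label = node$label, gene_id = node$gene_id,
      genome_order_index = node$genome_order_index,
      depth = depth, x = x, y = y, w = w, h = h,
      stringsAsFactors = FALSE
    )
    kids <- node$children
    if (!length(kids)) return(invisible())
    weights <- vapply(kids, `[[`, numeric(1), "weight")
    fracs <- weights / sum(weights)
    horizontal <- depth %% 2 == 0  # split along x at even depths
    offset <- 0
    for (i in seq_along(kids)) {
      if (horizontal) {
        recurse(kids[[i]], x + offset * w, y, fracs[i] * w, h, depth + 1L)
      } else {
        recurse(kids[[i]], x, y + offset * h, w, fracs[i] * h, depth + 1L)
      }
      offset <- offset + fracs[i]
    }
  }
  recurse(tree, canvas[1], canvas[2], canvas[3], canvas[4], 0L)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (minAspect > 0) {
    leaves <- out[out$level == "leaf", , drop = FALSE]
    aspect <- pmin(leaves$w, leaves$h) / pmax(leaves$w, leaves$h)
    if (any(aspect < minAspect))
      warning(sum(aspect < minAspect),
              " leaf cell(s) thinner than the requested aspect ratio")
  }
  out
}

#' Diverging color specification for expression ratios
#'
#' The blue-grey-orange ramp used for expression overlays: full blue at
#' `-clip` log2 units (decreased expression), mid grey at 0 (no change),
#' full orange at `+clip`, linear RGB interpolation in between, and a dark
#' grey for genes without assigned data.
#'
#' @param low,mid,high,missing colors (any form [grDevices::col2rgb()]
#'   accepts).
#' @param clip saturation point in absolute log2 units (default 2).
#' @return list used by [colorMap()] and [renderTreemap()].
#' @export
colorSpec <- function(low = "#2166AC", mid = "#BFBFBF", high = "#E66101",
                      clip = 2, missing = "#404040") {
  if (clip <= 0) stop("clip must be positive")
  list(low = low, mid = mid, high = high, clip = clip, missing = missing)
}

#' Map log2 ratios onto the diverging color ramp
#'
#' @param values numeric log2 ratios; NA means no assigned data.
#' @param spec a [colorSpec()].
#' @return character vector of hex colors.
#' @examples
#' colorMap(c(-3, 0, 1, NA))
#' @export
colorMap <- function(values, spec = colorSpec()) {
  ramp <- grDevices::colorRamp(c(spec$low, spec$mid, spec$high),
                               space = "rgb")
  out <- rep(spec$missing, length(values))
  ok <- !is.na(values)
  if (any(ok)) {
    t <- pmin(pmax(values[ok] / spec$clip, -1), 1) / 2 + 0.5
    out[ok] <- .rgbHex(ramp(t))
  }
  out
}

#' Render a treemap with transcript and protein overlays
#'
#' Writes a deterministic SVG: leaf cells filled by the protein log2
#' color (`class="cell"`), hierarchy borders over them (`class="border"`,
#' heavier strokes for higher levels), connector lines joining the circles
#' of genome-consecutive genes of the same operon (`class="connector"`,
#' colored by the mean mRNA value of the two linked genes) and a circle at
#' each leaf centroid colored by the gene's mRNA log2 (`class="gene"`).
#' Genes absent from the overlay are drawn in the missing-data dark grey.
#'
#' @param layout output of [layoutTreemap()].
#' @param overlay data.frame `gene_id`, `mrna_log2`, `protein_log2`
#'   (NA/absent rows allowed).
#' @param file output SVG path.
#' @param spec a [colorSpec()].
#' @param circleFrac circle radius as fraction of the shorter leaf-cell
#'   side (default 0.3).
#' @return the file path, invisibly.
#' @examples
#' ann <- simulateAnnotation(SimulationConfig(seed = 1, nGenes = 12))
#' layout <- layoutTreemap(buildHierarchy(ann), c(0, 0, 400, 300))
#' ov <- data.frame(gene_id = ann$gene_id, mrna_log2 = 0, protein_log2 = 1)
#' svg <- renderTreemap(layout, ov, tempfile(fileext = ".svg"))
#' @export
renderTreemap <- function(layout, overlay, file, spec = colorSpec(),
                          circleFrac = 0.3) {
  need <- c("gene_id", "mrna_log2", "protein_log2")
  if (!all(need %in% names(overlay)))
    stop("overlay needs columns ", paste(need, collapse = ", "))
  leaves <- layout[layout$level == "leaf", , drop = FALSE]
  idx <- match(leaves$gene_id, overlay$gene_id)
  protein <- overlay$protein_log2[idx]
  mrna <- overlay$mrna_log2[idx]

  root <- layout[layout$level == "root", , drop = FALSE]
  lines <- .svgOpen(root$x + root$w, root$y + root$h)
  # cells
  lines <- c(lines, mapply(.svgRect, leaves$x, leaves$y, leaves$w, leaves$h,
                           fill = colorMap(protein, spec),
                           MoreArgs = list(class = "cell")))
  # hierarchy borders, heavier for higher levels
  strokeW <- c(root = 2.5, main_role = 2.5, sub_role = 1.5, operon = 0.8,
               leaf = 0.3)
  for (lv in c("leaf", "operon", "sub_role", "main_role", "root")) {
    nd <- layout[layout$level == lv, , drop = FALSE]
    if (!nrow(nd)) next
    lines <- c(lines, mapply(.svgRect, nd$x, nd$y, nd$w, nd$h,
                             MoreArgs = list(fill = "none",
                                             stroke = "#FFFFFF",
                                             strokeWidth = strokeW[[lv]],
                                             class = "border")))
  }
  # connectors between genome-consecutive operon members, then circles
  operons <- layout$label[layout$level == "operon"]
  leafParent <- .leafOperon(layout)
  cx <- leaves$x + leaves$w / 2
  cy <- leaves$y + leaves$h / 2
  r <- circleFrac * pmin(leaves$w, leaves$h)
  for (op in unique(leafParent)) {
    members <- which(leafParent == op)
    members <- members[order(leaves$genome_order_index[members])]
    if (length(members) < 2L) next
    for (k in seq_len(length(members) - 1L)) {
      i <- members[k]; j <- members[k + 1L]
      mcol <- colorMap(mean(c(mrna[i], mrna[j])), spec)
      lines <- c(lines, .svgLine(cx[i], cy[i], cx[j], cy[j],
                                 stroke = mcol, strokeWidth = 1.2,
                                 class = "connector"))
    }
  }
  lines <- c(lines, mapply(.svgCircle, cx, cy, r,
                           fill = colorMap(mrna, spec),
                           MoreArgs = list(stroke = "#FFFFFF",
                                           class = "gene")))
  lines <- c(lines, .svgClose())
  writeLines(lines, file)
  invisible(file)
}

# operon label of each leaf row, by rectangle containment in layout order
.leafOperon <- function(layout) {
  leaves <- layout[layout$level == "leaf", , drop = FALSE]
  ops <- layout[layout$level == "operon", , drop = FALSE]
  eps <- 1e-9
  vapply(seq_len(nrow(leaves)), function(i) {
    inside <- ops$x <= leaves$x[i] + eps & ops$y <= leaves$y[i] + eps &
      ops$x + ops$w >= leaves$x[i] + leaves$w[i] - eps &
      ops$y + ops$h >= leaves$y[i] + leaves$h[i] - eps
    ops$label[which(inside)[1]]
  }, character(1))
}
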