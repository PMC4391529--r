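# Independent oracles, kept deliberately separate from the package code
# paths they check.

AA20 <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")

randomProtein <- function(len) paste(sample(AA20, len, TRUE), collapse = "")

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  get("BLOSUM62", envir = e)
})

# brute-force affine-gap local alignment score over the full DP matrices;
# a gap of length L costs open + L * ext
swOracleScore <- function(a, b, mat = blosum62, open = 11, ext = 1) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)
  F <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    E[i, j] <- max(H[i, j - 1] - open - ext, E[i, j - 1] - ext)
    F[i, j] <- max(H[i - 1, j] - open - ext, F[i - 1, j] - ext)
    H[i, j] <- max(0, H[i - 1, j - 1] + mat[a[i - 1], b[j - 1]],
                   E[i, j], F[i, j])
    best <- max(best, H[i, j])
  }
  best
}

# textbook pooled two-sample t-test, p via the incomplete beta function
tOracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  p <- pbeta(df / (df + t^2), df / 2, 1 / 2)
  list(t = t, p = p)
}

# row-by-row application of the printed DE rule, independent of callDE()
deOracle <- function(probes, threshold = 1) {
  repCols <- grep("^rep", names(probes), value = TRUE)
  out <- list()
  for (ct in unique(probes$contrast)) {
    for (g in unique(probes$gene_id)) {
      sub <- probes[probes$contrast == ct & probes$gene_id == g &
                      probes$offset >= 1, , drop = FALSE]
      status <- if (nrow(sub) == 0) "not_evaluated" else {
        means <- sapply(repCols, function(rc) mean(sub[[rc]]))
        if (all(means > threshold)) "up"
        else if (all(means < -threshold)) "down"
        else "unchanged"
      }
      out[[paste(ct, g)]] <- data.frame(gene_id = g, contrast = ct,
                                        status = status)
    }
  }
  do.call(rbind, out)
}

# geometric predicates for treemap layouts
rectArea <- function(r) r$w * r$h

rectsOverlapArea <- function(a, b) {
  ox <- max(0, min(a$x + a$w, b$x + b$w) - max(a$x, b$x))
  oy <- max(0, min(a$y + a$h, b$y + b$h) - max(a$y, b$y))
  ox * oy
}

rectInside <- function(inner, outer, eps = 1e-6) {
  inner$x >= outer$x - eps && inner$y >= outer$y - eps &&
    inner$x + inner$w <= outer$x + outer$w + eps &&
    inner$y + inner$h <= outer$y + outer$h + eps
}

rectsEdgeAdjacent <- function(a, b, eps = 1e-6) {
  touchX <- abs(a$x + a$w - b$x) < eps || abs(b$x + b$w - a$x) < eps
  overlapY <- min(a$y + a$h, b$y + b$h) - max(a$y, b$y) > eps
  touchY <- abs(a$y + a$h - b$y) < eps || abs(b$y + b$h - a$y) < eps
  overlapX <- min(a$x + a$w, b$x + b$w) - max(a$x, b$x) > eps
  (touchX && overlapY) || (touchY && overlapX)
}

# full geometric audit of a layout against its annotation; returns a list
# of logical results the tests assert on
auditLayout <- function(layout, annotation, canvas) {
  leaves <- layout[layout$level == "leaf", , drop = FALSE]
  n <- nrow(leaves)
  leafRect <- function(i) as.list(leaves[i, c("x", "y", "w", "h")])
  canvasRect <- list(x = canvas[1], y = canvas[2], w = canvas[3],
                     h = canvas[4])
  areas <- leaves$w * leaves$h
  expected <- canvas[3] * canvas[4] / n
  disjoint <- TRUE
  if (n > 1) for (i in 1:(n - 1)) for (j in (i + 1):n)
    if (rectsOverlapArea(leafRect(i), leafRect(j)) > 1e-6 * expected)
      disjoint <- FALSE
  contained <- all(vapply(seq_len(n), function(i)
    rectInside(leafRect(i), canvasRect), logical(1)))
  levelContained <- TRUE
  for (lv in c("operon", "sub_role", "main_role")) {
    nodeRects <- layout[layout$level == lv, , drop = FALSE]
    col <- c(operon = "operon_id", sub_role = "sub_role",
             main_role = "main_role")[[lv]]
    for (i in seq_len(n)) {
      lab <- annotation[[col]][annotation$gene_id == leaves$gene_id[i]]
      cand <- nodeRects[nodeRects$label == lab, , drop = FALSE]
      ok <- any(vapply(seq_len(nrow(cand)), function(k)
        rectInside(leafRect(i), as.list(cand[k, c("x", "y", "w", "h")])),
        logical(1)))
      if (!ok) levelContained <- FALSE
    }
  }
  adjacency <- TRUE
  ann <- annotation[order(annotation$genome_order_index), ]
  for (op in unique(ann$operon_id)) {
    genes <- ann$gene_id[ann$operon_id == op]
    if (length(genes) < 2) next
    for (k in 1:(length(genes) - 1)) {
      i <- which(leaves$gene_id == genes[k])
      j <- which(leaves$gene_id == genes[k + 1])
      if (!rectsEdgeAdjacent(leafRect(i), leafRect(j))) adjacency <- FALSE
    }
  }
  list(
    maxRelAreaError = max(abs(areas - expected) / expected),
    totalAreaError = abs(sum(areas) - canvas[3] * canvas[4]) /
      (canvas[3] * canvas[4]),
    disjoint = disjoint,
    contained = contained && levelContained,
    adjacency = adjacency
  )
}

countSvgElements <- function(file) {
  txt <- readLines(file)
  c(cells = sum(grepl("class=\"cell\"", txt)),
    genes = sum(grepl("class=\"gene\"", txt)),
    connectors = sum(grepl("class=\"connector\"", txt)))
}
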