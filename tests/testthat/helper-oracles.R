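# Independent oracle implementations used to cross-check the package.
# These deliberately share no code with the implementation: recursive
# flood fill instead of the compiled labeler, explicit sums-of-squares
# instead of aov(), per-voxel loops instead of vectorized tallies.

# Brute-force connected components by repeated flood fill over an explicit
# frontier, scanning all 26 neighbor offsets and filtering by order.
oracleLabelComponents <- function(mask, connectivity) {
  d <- dim(mask)
  offs <- expand.grid(di = -1:1, dj = -1:1, dk = -1:1)
  ord <- abs(offs$di) + abs(offs$dj) + abs(offs$dk)
  offs <- offs[ord > 0 & ord <= c("6" = 1, "18" = 2, "26" = 3)[as.character(connectivity)], ]
  labels <- array(0L, dim = d)
  cur <- 0L
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    if (!mask[i, j, k] || labels[i, j, k] != 0L) next
    cur <- cur + 1L
    frontier <- matrix(c(i, j, k), ncol = 3)
    labels[i, j, k] <- cur
    while (nrow(frontier) > 0) {
      nxt <- list()
      for (r in seq_len(nrow(frontier))) {
        for (o in seq_len(nrow(offs))) {
          p <- frontier[r, ] + c(offs$di[o], offs$dj[o], offs$dk[o])
          if (any(p < 1) || any(p > d)) next
          if (mask[p[1], p[2], p[3]] && labels[p[1], p[2], p[3]] == 0L) {
            labels[p[1], p[2], p[3]] <- cur
            nxt[[length(nxt) + 1]] <- p
          }
        }
      }
      frontier <- if (length(nxt)) do.call(rbind, nxt) else
        matrix(numeric(0), ncol = 3)
    }
  }
  labels
}

# Voxel sets (as sorted linear index lists) from a label volume, order-free.
componentSets <- function(labels) {
  ids <- setdiff(sort(unique(as.vector(labels))), 0L)
  sets <- lapply(ids, function(id) sort(which(labels == id)))
  # canonical order: by smallest member
  sets[order(vapply(sets, min, numeric(1)))]
}

# Per-voxel overlap tally with explicit loops.
oracleTally <- function(masks) {
  d <- dim(masks[[1]])
  counts <- array(0L, dim = d)
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    n <- 0L
    for (m in masks) if (m[i, j, k]) n <- n + 1L
    counts[i, j, k] <- n
  }
  counts
}

# Classical mixed-design ANOVA interaction F from explicit sums of squares
# (balanced groups; T within levels, G groups, n subjects per group).
oracleMixedAnovaF <- function(y, group, threshold, subject) {
  subjects <- unique(subject)
  groups <- unique(group)
  thresholds <- unique(threshold)
  G <- length(groups); Tn <- length(thresholds); N <- length(subjects)
  groupOf <- vapply(subjects, function(s) unique(group[subject == s]), group[1])
  cellMean <- function(g, t) mean(y[group == g & threshold == t])
  groupMean <- function(g) mean(y[group == g])
  subjMean <- function(s) mean(y[subject == s])
  threshMeanWithin <- function(t) mean(vapply(groups, function(g)
    cellMean(g, t), numeric(1)))
  grandCell <- mean(vapply(groups, groupMean, numeric(1)))
  nPerGroup <- vapply(groups, function(g) sum(groupOf == g), numeric(1))
  ssInt <- 0
  for (gi in seq_along(groups)) for (t in thresholds) {
    dev <- cellMean(groups[gi], t) - groupMean(groups[gi]) -
      threshMeanWithin(t) + grandCell
    ssInt <- ssInt + nPerGroup[gi] * dev^2
  }
  ssErr <- 0
  for (si in seq_along(subjects)) for (t in thresholds) {
    s <- subjects[si]; g <- groupOf[si]
    dev <- y[subject == s & threshold == t] - subjMean(s) -
      cellMean(g, t) + groupMean(g)
    ssErr <- ssErr + dev^2
  }
  df1 <- (G - 1) * (Tn - 1)
  df2 <- (Tn - 1) * (N - G)
  unname((ssInt / df1) / (ssErr / df2))
}

# Hand-computed one-sample t.
oracleOneSampleT <- function(x) {
  mean(x) / (sd(x) / sqrt(length(x)))
}

randomScalarVolume <- function(dims = c(16L, 16L, 16L), voxelSize = c(1, 1, 1)) {
  ScalarVolume(array(rnorm(prod(dims)), dim = dims), voxelSize)
}

smallConfig <- function(...) {
  phantomConfig(dims = c(24L, 24L, 20L), voxelSize = c(2, 2, 2),
                knobCenterMM = c(7, 1, 1), knobRadiiMM = c(4, 4, 4),
                maskSemiAxesMM = c(19, 20, 16), ...)
}
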