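#' Group-difference and structure statistics
#'
#' Post-quantification analyses of the samples-by-metabolites table:
#' z-scaling (per metabolite or globally), one-way ANOVA feature ranking
#' with the conventional F > 5 panel rule, PCA by singular value
#' decomposition, deterministic hierarchical leaf ordering for heat maps,
#' metabolite-metabolite correlation-difference maps between two sample
#' pools, and hypergeometric pathway over-representation.
#'
#' @name statistics
NULL

asConcMatrix <- function(table) {
  if (is(table, "ConcentrationTable")) concentrations(table)
  else as.matrix(table)
}

#' Z-scale a concentration table
#'
#' `per_metabolite` standardizes each metabolite column to mean 0 and
#' standard deviation 1 across samples; `global` standardizes the whole
#' matrix by its grand mean and grand standard deviation. Zero-variance
#' columns map to 0 with a warning. The result can contain negative values,
#' so it is returned as a plain matrix rather than a ConcentrationTable.
#'
#' @param table a [ConcentrationTable-class] or samples x metabolites matrix.
#' @param mode `"per_metabolite"` or `"global"`.
#' @return Scaled samples x metabolites matrix.
#' @export
zscale <- function(table, mode = c("per_metabolite", "global")) {
  mode <- match.arg(mode)
  x <- asConcMatrix(table)
  if (nrow(x) < 2L) stop("z-scaling needs at least 2 samples")
  if (mode == "per_metabolite") {
    mu <- colMeans(x)
    sdv <- apply(x, 2, sd)
    flat <- sdv == 0 | !is.finite(sdv)
    if (any(flat)) {
      warning("zero-variance column(s) set to 0: ",
              paste(colnames(x)[flat], collapse = ", "))
      sdv[flat] <- 1
    }
    out <- sweep(sweep(x, 2, mu), 2, sdv, `/`)
    out[, flat] <- 0
    out
  } else {
    s <- sd(as.numeric(x))
    if (s == 0) stop("constant table cannot be globally scaled")
    (x - mean(x)) / s
  }
}

#' Rank metabolites by one-way ANOVA F statistic
#'
#' Computes the classic one-way F (between-group over within-group mean
#' square) per metabolite and sorts descending. The panel rule retains
#' features with F above the threshold (5 by convention for the main panels,
#' 3 for subtler contrasts). Groups with zero within-group variance and a
#' real between-group difference yield `Inf`, which sorts first.
#'
#' @param table a [ConcentrationTable-class] or samples x metabolites matrix.
#' @param labels class label per sample, or (for a ConcentrationTable) the
#'   name of a `colData` column such as `"sourceType"`.
#' @param threshold panel selection threshold on F.
#' @return data.frame with columns `metabolite`, `fStatistic`, `rank`,
#'   `selected`, sorted by descending F (ties keep input order).
#' @export
anovaRank <- function(table, labels, threshold = 5) {
  x <- asConcMatrix(table)
  if (is(table, "ConcentrationTable") && length(labels) == 1L &&
      labels %in% colnames(SummarizedExperiment::colData(table)))
    labels <- SummarizedExperiment::colData(table)[[labels]]
  g <- factor(labels)
  if (length(g) != nrow(x))
    stop("labels length must match the number of samples")
  cnt <- base::table(g)   # `table` is shadowed by the data argument
  if (nlevels(g) < 2L) stop("at least 2 classes are required")
  small <- names(cnt)[cnt < 2L]
  if (length(small))
    stop("class(es) with fewer than 2 samples: ",
         paste(small, collapse = ", "))
  fstat <- vapply(seq_len(ncol(x)), function(j) {
    y <- x[, j]
    gm <- tapply(y, g, mean)
    ssb <- sum(cnt * (gm - mean(y))^2)
    ssw <- sum((y - gm[g])^2)
    dfb <- nlevels(g) - 1L
    dfw <- length(y) - nlevels(g)
    msb <- ssb / dfb
    msw <- ssw / dfw
    if (msw == 0) { if (msb == 0) 0 else Inf } else msb / msw
  }, numeric(1))
  o <- order(-fstat, seq_along(fstat))
  data.frame(metabolite = colnames(x)[o], fStatistic = fstat[o],
             rank = seq_along(o), selected = fstat[o] > threshold,
             row.names = NULL)
}

#' Principal component analysis by SVD
#'
#' Column-centers the matrix and decomposes it with [stats::prcomp()].
#'
#' @param x samples x features matrix or [ConcentrationTable-class].
#' @param nComponents number of components to keep.
#' @return `list(scores, loadings, explainedVariance, center)`;
#'   `explainedVariance` holds the per-component fractions of total
#'   variance (all components, not just those kept).
#' @export
runPCA <- function(x, nComponents = 2L) {
  x <- asConcMatrix(x)
  if (nrow(x) < 2L) stop("PCA needs at least 2 samples")
  if (nComponents > min(dim(x)))
    stop("nComponents exceeds min(dim(x))")
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x[, seq_len(nComponents), drop = FALSE],
       loadings = pc$rotation[, seq_len(nComponents), drop = FALSE],
       explainedVariance = ev,
       center = pc$center)
}

#' Deterministic hierarchical leaf ordering
#'
#' Agglomerative clustering of metabolites or samples for heat-map display.
#'
#' @param table a [ConcentrationTable-class] or samples x metabolites matrix.
#' @param axis cluster `"metabolites"` (columns) or `"samples"` (rows).
#' @param distance `"euclidean"` or `"correlation"` (1 - Pearson r).
#' @param linkage `"average"` or `"complete"`.
#' @return Integer leaf order (1-based indices into the chosen axis).
#' @export
hierarchicalOrder <- function(table, axis = c("metabolites", "samples"),
                              distance = c("euclidean", "correlation"),
                              linkage = c("average", "complete")) {
  axis <- match.arg(axis); distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  x <- asConcMatrix(table)
  items <- if (axis == "metabolites") t(x) else x
  if (nrow(items) < 2L) stop("need at least 2 items to order")
  d <- if (distance == "euclidean") dist(items)
       else as.dist(1 - cor(t(items)))
  hclust(d, method = linkage)$order
}

#' Correlation-difference map between two sample pools
#'
#' Computes the Pearson correlation matrix of metabolites within each pool
#' (e.g. one cell line's vesicle and media samples vs another's) and returns
#' their difference: positive entries mean a stronger correlation in pool A.
#'
#' @param tableA,tableB [ConcentrationTable-class] or matrices with the same
#'   metabolite columns and at least 3 samples each.
#' @return Symmetric metabolites x metabolites matrix of `r_A - r_B` with a
#'   zero diagonal; rows/columns of zero-variance metabolites are `NA` (with
#'   a warning).
#' @export
correlationDifference <- function(tableA, tableB) {
  a <- asConcMatrix(tableA); b <- asConcMatrix(tableB)
  if (!identical(colnames(a), colnames(b)))
    stop("tables must share identical metabolite columns")
  if (nrow(a) < 3L || nrow(b) < 3L)
    stop("each pool needs at least 3 samples")
  flat <- apply(a, 2, sd) == 0 | apply(b, 2, sd) == 0
  if (any(flat))
    warning("zero-variance metabolite(s) set to NA: ",
            paste(colnames(a)[flat], collapse = ", "))
  ra <- suppressWarnings(cor(a)); rb <- suppressWarnings(cor(b))
  dr <- ra - rb
  dr[flat, ] <- NA_real_; dr[, flat] <- NA_real_
  diag(dr) <- 0
  dr
}

#' Hypergeometric pathway over-representation
#'
#' For each pathway, the upper-tail hypergeometric probability of observing
#' at least the actual overlap between the selected set and the pathway
#' members, given the universe of measured identifiers.
#'
#' @param selected character set of selected identifiers (subset of
#'   `universe`).
#' @param pathways named list of character vectors (e.g. from [readGMT()]).
#' @param universe character set of all measured identifiers.
#' @param adjust apply Benjamini-Hochberg correction (off by default; the
#'   raw test is reported unless asked otherwise).
#' @return data.frame with `pathway`, `pathwaySize` (after intersection with
#'   the universe), `overlap`, `pValue` (and `pAdjusted` when `adjust`).
#' @export
oraHypergeometric <- function(selected, pathways, universe, adjust = FALSE) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe")
  selected <- unique(selected)
  if (!all(selected %in% universe))
    stop("selected identifiers must be a subset of the universe")
  N <- length(universe); n <- length(selected)
  res <- lapply(names(pathways), function(pw) {
    members <- intersect(unique(pathways[[pw]]), universe)
    K <- length(members)
    k <- length(intersect(members, selected))
    p <- if (k == 0L) 1.0 else phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(pathway = pw, pathwaySize = K, overlap = k, pValue = p)
  })
  out <- do.call(rbind, res)
  if (adjust) out$pAdjusted <- p.adjust(out$pValue, method = "BH")
  out[order(out$pValue), , drop = FALSE]
}

#' Read pathway sets from a GMT file
#'
#' Standard tab-separated gene-set format: name, description, members.
#'
#' @param path GMT file path.
#' @return Named list of character vectors.
#' @export
readGMT <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3L)
      stop("malformed GMT line (need name, description, >=1 member): ", l)
    parts[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1), USE.NAMES = FALSE)
  sets
}
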