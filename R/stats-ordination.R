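# Ordination and statistics on functional profiles: Spearman correlation
# matrices, agglomerative clustering on d = 1 - rho, PCA of (optionally
# log-transformed) abundance profiles, and Kruskal-Wallis group tests.

#' Pairwise Spearman correlation of samples or families
#'
#' Computes Spearman rank correlation (average ranks for ties) between the
#' sample columns or family rows of an abundance matrix, on UNTRANSFORMED
#' abundances - ranks are invariant to the `log10(x + 0.5)` display
#' transform, so transforming first would change nothing. Constant vectors
#' have undefined correlations; those pairs are NA and flagged.
#'
#' @param mat abundance matrix (families x samples).
#' @param axis correlate `"samples"` (columns) or `"families"` (rows).
#' @return object of class `spearman_cor`: list with `labels`, `rho` (the
#'   correlation matrix, unit diagonal) and `undefined` (labels of
#'   constant vectors).
#' @export
spearman_matrix <- function(mat, axis = c("samples", "families")) {
  axis <- match.arg(axis)
  m <- if (axis == "samples") unclass(mat) else t(unclass(mat))
  if (ncol(m) < 2L) stop("need at least 2 vectors to correlate", call. = FALSE)
  constant <- apply(m, 2L, function(v) length(unique(v)) == 1L)
  rho <- suppressWarnings(cor(m, method = "spearman"))
  diag(rho) <- 1
  structure(list(labels = colnames(m), rho = rho,
                 undefined = colnames(m)[constant], axis = axis),
            class = "spearman_cor")
}

#' @export
print.spearman_cor <- function(x, ...) {
  cat(sprintf("spearman_cor: %d %s\n", length(x$labels), x$axis))
  if (length(x$undefined))
    cat("undefined (constant) vectors:", paste(x$undefined, collapse = ", "), "\n")
  print(round(x$rho[seq_len(min(6L, nrow(x$rho))),
                    seq_len(min(6L, ncol(x$rho))), drop = FALSE], 3))
  invisible(x)
}

#' Hierarchical clustering of correlation profiles
#'
#' Agglomerative clustering on the distance `d = 1 - rho` (not `1 - |rho|`:
#' anti-correlated profiles should separate). Labels are put in
#' lexicographic order before clustering so that tied merges resolve
#' identically regardless of input column order.
#'
#' @param corr a [spearman_matrix()] result.
#' @param linkage `"complete"` (default, the base `hclust` convention
#'   here), `"average"` or `"single"`.
#' @return an `hclust` object; leaf order for heatmap axes is in
#'   `$order`/`$labels`.
#' @export
cluster_profiles <- function(corr, linkage = c("complete", "average", "single")) {
  linkage <- match.arg(linkage)
  if (length(corr$undefined))
    stop(sprintf(paste("undefined correlations for constant profile(s) %s;",
                       "apply prevalence_filter() or drop them first"),
                 paste(corr$undefined, collapse = ", ")), call. = FALSE)
  ord <- order(corr$labels)
  d <- as.dist(1 - corr$rho[ord, ord])
  hclust(d, method = linkage)
}

#' Write a dendrogram in Newick format
#'
#' @param hc an `hclust` object from [cluster_profiles()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dendrogram <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' PCA of abundance profiles
#'
#' Principal component analysis of sample profiles: samples are
#' observations, families are variables. By default the display transform
#' `log10(x + 0.5)` is applied first and variables are centered but not
#' scaled. Component signs follow a deterministic convention (the
#' largest-magnitude loading of each component is positive).
#'
#' @param mat abundance matrix (families x samples).
#' @param transform `"log"` for `log10(x + 0.5)` (default) or `"none"`.
#' @param center,scale. passed to the underlying decomposition.
#' @return object of class `enz_pca`: list with `scores` (samples x PC),
#'   `loadings` (families x PC), `explained_variance_fraction`, `transform`.
#' @export
pca_profiles <- function(mat, transform = c("log", "none"), center = TRUE,
                         scale. = FALSE) {
  transform <- match.arg(transform)
  x <- t(unclass(mat))
  if (nrow(x) < 2L) stop("PCA needs at least 2 samples", call. = FALSE)
  if (transform == "log") x <- log10(x + 0.5)
  p <- prcomp(x, center = center, scale. = scale.)
  for (j in seq_len(ncol(p$rotation))) {
    i <- which.max(abs(p$rotation[, j]))
    if (p$rotation[i, j] < 0) {
      p$rotation[, j] <- -p$rotation[, j]
      p$x[, j] <- -p$x[, j]
    }
  }
  ev <- p$sdev^2
  structure(list(scores = p$x, loadings = p$rotation,
                 explained_variance_fraction = ev / sum(ev),
                 transform = transform),
            class = "enz_pca")
}

#' @export
print.enz_pca <- function(x, ...) {
  k <- min(5L, length(x$explained_variance_fraction))
  cat(sprintf("enz_pca: %d samples, %d variables (transform: %s)\n",
              nrow(x$scores), nrow(x$loadings), x$transform))
  cat("explained variance fraction:",
      paste(sprintf("PC%d %.3f", seq_len(k),
                    x$explained_variance_fraction[seq_len(k)]),
            collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.enz_pca <- function(x, components = c(1L, 2L), groups = NULL, ...) {
  s <- x$scores[, components, drop = FALSE]
  ev <- x$explained_variance_fraction[components]
  col <- if (is.null(groups)) "black" else as.integer(factor(groups))
  plot(s, col = col, pch = 19,
       xlab = sprintf("PC%d (%.1f%%)", components[1L], 100 * ev[1L]),
       ylab = sprintf("PC%d (%.1f%%)", components[2L], 100 * ev[2L]), ...)
  if (!is.null(groups))
    legend("topright", legend = levels(factor(groups)), col =
             seq_along(levels(factor(groups))), pch = 19, cex = 0.7)
  invisible(x)
}

#' Kruskal-Wallis rank-sum test
#'
#' Thin wrapper around the base test with the conventions used for the
#' province comparisons: the tie-corrected H statistic, a chi-square
#' p-value on groups - 1 degrees of freedom, an explicit error for a
#' single group, and the degenerate all-tied case (every observation
#' equal) reported as H = 0, p = 1 rather than 0/0.
#'
#' @param values numeric observations.
#' @param groups group labels, same length.
#' @param label optional feature label carried through to the result.
#' @return object of class `kruskal_result`: list with `statistic` (H),
#'   `df`, `p.value`, `label`.
#' @export
kruskal_wallis <- function(values, groups, label = NULL) {
  groups <- as.factor(as.character(groups))
  if (nlevels(groups) < 2L)
    stop("Kruskal-Wallis needs at least 2 groups", call. = FALSE)
  if (any(tabulate(groups) == 0L))
    stop("every group must be non-empty", call. = FALSE)
  df <- nlevels(groups) - 1L
  if (length(unique(values)) == 1L) {
    res <- list(statistic = 0, df = df, p.value = 1, label = label)
  } else {
    kt <- kruskal.test(values, groups)
    res <- list(statistic = unname(kt$statistic), df = unname(kt$parameter),
                p.value = kt$p.value, label = label)
  }
  class(res) <- "kruskal_result"
  res
}

#' @export
print.kruskal_result <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis%s: H = %.4g, df = %d, p = %.4g\n",
              if (is.null(x$label)) "" else paste0(" [", x$label, "]"),
              x$statistic, x$df, x$p.value))
  invisible(x)
}

#' Clustered heatmap of an abundance matrix
#'
#' Draws the standard functional-profile heatmap: display-transformed
#' abundances (`log10(x + 0.5)`) with rows and columns ordered by
#' Spearman-correlation clustering of the untransformed matrix.
#'
#' @param mat abundance matrix (families x samples).
#' @param linkage linkage method for [cluster_profiles()].
#' @param ... passed to [stats::heatmap()].
#' @return invisibly, the list of row/column `hclust` objects.
#' @export
plot_abundance_heatmap <- function(mat, linkage = "complete", ...) {
  hc_samples <- cluster_profiles(spearman_matrix(mat, "samples"), linkage)
  hc_families <- cluster_profiles(spearman_matrix(mat, "families"), linkage)
  stats::heatmap(viz_transform(mat),
                 Rowv = as.dendrogram(hc_families),
                 Colv = as.dendrogram(hc_samples), scale = "none", ...)
  invisible(list(samples = hc_samples, families = hc_families))
}
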