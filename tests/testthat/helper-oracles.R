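# Independent oracles used to cross-check the implementation. These stay
# deliberately naive (loops, closed forms, exhaustive enumeration) and
# never call the code paths they verify.

# gene-by-gene accumulation of the normalized abundance matrix
brute_force_matrix <- function(annots, gene_map, coverage, assembly_stats,
                               scheme) {
  ann <- annots[annots$scheme == scheme, , drop = FALSE]
  samples <- assembly_stats$sample_id
  families <- sort(unique(ann$label))
  out <- matrix(0, length(families), length(samples),
                dimnames = list(families, samples))
  for (i in seq_len(nrow(ann))) {
    g <- ann$gene_id[i]
    contig <- if (g %in% names(gene_map)) gene_map[[g]] else
      sub("_[^_]*$", "", g)
    depth <- coverage$mean_depth[coverage$contig_id == contig]
    total <- assembly_stats$total_length[assembly_stats$sample_id == ann$sample_id[i]]
    out[ann$label[i], ann$sample_id[i]] <-
      out[ann$label[i], ann$sample_id[i]] + depth * 1e9 / total
  }
  out
}

# naive complete/average/single-linkage agglomeration on a distance matrix;
# returns the sorted merge heights
naive_linkage_heights <- function(d, linkage = "complete") {
  d <- as.matrix(d)
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- c(Inf, NA, NA)
    for (a in seq_along(clusters)) for (b in seq_len(a - 1L)) {
      dd <- d[clusters[[a]], clusters[[b]], drop = FALSE]
      h <- switch(linkage, complete = max(dd), average = mean(dd),
                  single = min(dd))
      if (h < best[1L]) best <- c(h, a, b)
    }
    heights <- c(heights, best[1L])
    merged <- c(clusters[[best[2L]]], clusters[[best[3L]]])
    clusters <- clusters[-c(best[2L], best[3L])]
    clusters[[length(clusters) + 1L]] <- merged
  }
  sort(heights)
}

# covariance eigendecomposition PCA oracle: X has samples as rows
eigen_pca_oracle <- function(x, center = TRUE) {
  xc <- scale(x, center = center, scale = FALSE)
  cv <- crossprod(xc) / (nrow(xc) - 1L)
  e <- eigen(cv, symmetric = TRUE)
  list(scores = xc %*% e$vectors, variance = e$values,
       fraction = e$values / sum(e$values))
}

# tie-corrected Kruskal-Wallis H from the general rank-statistic form
rank_statistic_h <- function(values, groups) {
  r <- rank(values)
  n <- length(r)
  rbar <- mean(r)
  num <- sum(tapply(r, groups, function(ri) length(ri) * (mean(ri) - rbar)^2))
  den <- sum((r - rbar)^2)
  (n - 1) * num / den
}

# Spearman rho via the classical no-ties formula
spearman_no_ties <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

write_lines_tmp <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

# a small, quick study configuration shared across tests
small_config <- function(...) {
  simulation_config(n_sites = 3, n_contigs_per_sample = 25,
                    genes_per_contig = 6, seed = 42, ...)
}

# noise-free configuration: every gene is a grouped, secreted,
# two-tool CAZyme on a constant-depth contig
noise_free_config <- function(n_sites = 2, n_contigs = 250,
                              genes_per_contig = 20, ratio = 0.7, seed = 101) {
  simulation_config(
    n_sites = n_sites, n_contigs_per_sample = n_contigs,
    genes_per_contig = genes_per_contig,
    scheme_probs = c(CAZY = 1, MEROPS = 0, EC = 0),
    group_gene_prob = 1, cell_vs_photo_ratio = ratio,
    secreted_prob = 1, two_tool_prob = 1, depth_dist = NULL,
    hightemp_depauperation = 1, seed = seed)
}

count_annotation_rows <- function(study, sid) {
  n_overview <- nrow(read.delim(study$files[[sid]][["cazy_overview"]],
                                check.names = FALSE))
  n_dram <- nrow(read.delim(study$files[[sid]][["annotations"]]))
  n_overview + n_dram
}
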