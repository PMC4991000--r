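#' Gene-gene Pearson correlation matrix
#'
#' @param study An `ExpressionStudy` with >= 4 samples (the Fisher
#'   significance test requires n > 3). Genes with zero variance across
#'   samples are an error — run [variance_filter()] first.
#' @return Symmetric gene-by-gene correlation matrix with unit diagonal.
#' @export
pearson_matrix <- function(study) {
  stopifnot(inherits(study, "ExpressionStudy"))
  if (ncol(study$values) < 4)
    stop("correlation significance requires >= 4 samples")
  v <- apply(study$values, 1, var)
  if (any(v == 0))
    stop("zero-variance gene(s): ",
         paste(rownames(study$values)[v == 0], collapse = ", "),
         " (apply variance_filter first)")
  cor(t(study$values))
}

#' Fisher z-transformation p-value for a Pearson correlation
#'
#' Two-sided p-value of the asymptotic test of r = 0:
#' `z = atanh(r) * sqrt(n - 3)` compared against the standard normal.
#' `|r| = 1` returns `p = 0` by convention.
#'
#' @param r Correlation value(s) in \[-1, 1\] (vectorised).
#' @param n Sample count, must exceed 3.
#' @return p-value(s) in \[0, 1\].
#' @export
fisher_corr_pvalue <- function(r, n) {
  if (any(n <= 3)) stop("Fisher's asymptotic test requires n > 3")
  if (any(abs(r) > 1 + 1e-12)) stop("correlations must lie in [-1, 1]")
  r <- pmin(1, pmax(-1, r))
  p <- 2 * pnorm(-abs(atanh(r)) * sqrt(n - 3))
  p[abs(r) == 1] <- 0
  p
}

#' Exact-t p-value for a Pearson correlation
#'
#' Alternative small-sample test: `t = r * sqrt((n-2)/(1-r^2))` on
#' `n - 2` degrees of freedom.
#'
#' @inheritParams fisher_corr_pvalue
#' @return p-value(s) in \[0, 1\].
#' @export
exact_t_corr_pvalue <- function(r, n) {
  if (any(n <= 3)) stop("requires n > 3")
  r <- pmin(1, pmax(-1, r))
  p <- 2 * pt(-abs(r) * sqrt((n - 2) / pmax(1 - r^2, 0)), n - 2)
  p[abs(r) == 1] <- 0
  p
}

#' Per-gene top/bottom percentile edge mask
#'
#' For each gene g, flags partner h when `r[g,h]` lies at or above the
#' `1 - q` quantile, or at or below the `q` quantile, of g's off-diagonal
#' correlations (linear-interpolation quantiles). The mask is directional:
#' `mask[g, h]` says h passes from g's viewpoint; combine with its
#' transpose for a symmetric rule.
#'
#' @param corr Symmetric correlation matrix.
#' @param q Percentile fraction in (0, 0.5); default 0.05.
#' @return Logical matrix, diagonal `FALSE`.
#' @export
percentile_edge_mask <- function(corr, q = 0.05) {
  if (!is.numeric(q) || length(q) != 1 || q <= 0 || q >= 0.5)
    stop("'q' must be in (0, 0.5)")
  n <- nrow(corr)
  mask <- matrix(FALSE, n, n, dimnames = dimnames(corr))
  for (g in seq_len(n)) {
    vals <- corr[g, -g]
    lo <- quantile(vals, q, names = FALSE)
    hi <- quantile(vals, 1 - q, names = FALSE)
    mask[g, -g] <- vals >= hi | vals <= lo
  }
  mask
}

#' Build the coding-non-coding co-expression network
#'
#' An undirected simple graph over coding and lncRNA genes. An edge (g, h)
#' is included when all enabled criteria hold:
#' * `|r_gh| >= pcc_cutoff` (hard correlation cutoff; default 0.93),
#' * Bonferroni-adjusted correlation p-value `<= alpha` (multiplier =
#'   number of tested pairs, `choose(n_genes, 2)`; default alpha 0.01),
#' * the per-gene percentile rule ([percentile_edge_mask()]) holds at
#'   both endpoints (`endpoint_rule = "both"`, default) or at least one
#'   (`"either"`).
#'
#' Any criterion can be disabled by passing `NULL`. Edges are classified
#' `CC` (coding-coding), `CN` (coding-noncoding) or `NN`
#' (noncoding-noncoding); the node set is the genes incident to at least
#' one edge.
#'
#' @param study An `ExpressionStudy`, typically pre-filtered with
#'   [variance_filter()].
#' @param pcc_cutoff Absolute correlation cutoff, or `NULL` to disable.
#' @param alpha Bonferroni-adjusted p threshold, or `NULL` to disable.
#' @param q Percentile fraction for the per-gene rule, or `NULL`.
#' @param endpoint_rule `"both"` or `"either"`.
#' @param correlation_test `"fisher_z"` (default) or `"exact_t"`.
#' @return A `CNCNetwork`: list with `nodes` (data frame `gene_id`,
#'   `biotype`, `degree`) and `edges` (data frame `gene_a`, `gene_b`,
#'   `pcc`, `p_raw`, `p_bonferroni`, `class`), plus `n_tested_pairs`.
#' @export
build_network <- function(study, pcc_cutoff = 0.93, alpha = 0.01,
                          q = 0.05, endpoint_rule = c("both", "either"),
                          correlation_test = c("fisher_z", "exact_t")) {
  endpoint_rule <- match.arg(endpoint_rule)
  correlation_test <- match.arg(correlation_test)
  r <- pearson_matrix(study)
  genes <- rownames(r)
  ng <- length(genes)
  ns <- ncol(study$values)
  ut <- which(upper.tri(r))
  npairs <- length(ut)

  pfun <- if (correlation_test == "fisher_z") fisher_corr_pvalue
          else exact_t_corr_pvalue
  p_raw <- pfun(r[ut], ns)
  p_bonf <- pmin(1, p_raw * npairs)

  keep <- rep(TRUE, npairs)
  if (!is.null(pcc_cutoff)) keep <- keep & abs(r[ut]) >= pcc_cutoff
  if (!is.null(alpha)) keep <- keep & p_bonf <= alpha
  if (!is.null(q)) {
    m <- percentile_edge_mask(r, q)
    msym <- if (endpoint_rule == "both") m & t(m) else m | t(m)
    keep <- keep & msym[ut]
  }

  idx <- ut[keep]
  ai <- ((idx - 1L) %% ng) + 1L   # row index of upper-tri entry
  bi <- ((idx - 1L) %/% ng) + 1L  # column index
  bt <- study$biotype
  cls <- ifelse(bt[ai] == "coding" & bt[bi] == "coding", "CC",
         ifelse(bt[ai] == "lncRNA" & bt[bi] == "lncRNA", "NN", "CN"))
  edges <- data.frame(gene_a = genes[ai], gene_b = genes[bi],
                      pcc = r[idx], p_raw = p_raw[keep],
                      p_bonferroni = p_bonf[keep],
                      class = unname(cls), stringsAsFactors = FALSE)
  node_ids <- genes[genes %in% c(edges$gene_a, edges$gene_b)]
  deg <- table(factor(c(edges$gene_a, edges$gene_b), levels = node_ids))
  nodes <- data.frame(gene_id = node_ids,
                      biotype = unname(bt[node_ids]),
                      degree = as.integer(deg),
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges, n_tested_pairs = npairs),
            class = "CNCNetwork")
}

#' @export
print.CNCNetwork <- function(x, ...) {
  s <- network_summary(x)
  cat("CNCNetwork:", s$n_coding, "coding +", s$n_lncRNA, "lncRNA nodes;",
      s$n_edges, "edges (CC", s$n_CC, "/ CN", s$n_CN, "/ NN", s$n_NN,
      ")\n")
  invisible(x)
}

#' Summarise a CNC network
#'
#' @param net A `CNCNetwork`.
#' @return A list with node counts by biotype (`n_coding`, `n_lncRNA`)
#'   and edge counts by class (`n_CC`, `n_CN`, `n_NN`, `n_edges`).
#' @export
network_summary <- function(net) {
  stopifnot(inherits(net, "CNCNetwork"))
  list(n_coding = sum(net$nodes$biotype == "coding"),
       n_lncRNA = sum(net$nodes$biotype == "lncRNA"),
       n_edges = nrow(net$edges),
       n_CC = sum(net$edges$class == "CC"),
       n_CN = sum(net$edges$class == "CN"),
       n_NN = sum(net$edges$class == "NN"))
}

#' Convert a CNC network to an igraph graph
#'
#' Node biotype and edge attributes (`pcc`, `class`) are carried over;
#' useful for GraphML export and topology queries.
#'
#' @param net A `CNCNetwork`.
#' @return An undirected `igraph` graph.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "CNCNetwork"))
  igraph::graph_from_data_frame(
    net$edges[, c("gene_a", "gene_b", "pcc", "class")],
    directed = FALSE,
    vertices = net$nodes[, c("gene_id", "biotype")])
}

#' Export a CNC network
#'
#' Writes the edge list (`gene_a, gene_b, pcc, p_raw, p_bonferroni,
#' class`) and node list (`gene_id, biotype, degree`) as TSV, and
#' optionally a GraphML file for network viewers.
#'
#' @param net A `CNCNetwork`.
#' @param edge_path,node_path TSV output paths.
#' @param graphml_path Optional GraphML output path.
#' @return Invisibly, `net`.
#' @export
write_network <- function(net, edge_path, node_path,
                          graphml_path = NULL) {
  write.table(net$edges, edge_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(net$nodes, node_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(graphml_path))
    igraph::write_graph(as_igraph(net), graphml_path, format = "graphml")
  invisible(net)
}
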