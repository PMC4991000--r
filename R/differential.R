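#' Benjamini-Hochberg step-up adjustment
#'
#' Thin validated wrapper around `p.adjust(method = "BH")`, kept as a
#' named operation because the adjusted values feed the reversal filter.
#'
#' @param pvals Numeric vector of raw p-values in \[0, 1\].
#' @return Adjusted p-values in input order, with step-up monotonicity
#'   enforced.
#' @export
bh_adjust <- function(pvals) {
  if (!is.numeric(pvals))
    stop("'pvals' must be numeric")
  if (any(!is.finite(pvals)) || any(pvals < 0) || any(pvals > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(pvals, method = "BH")
}

#' Two-condition differential expression contrast
#'
#' Tests every gene for a mean log2 expression difference between a
#' treatment and a reference condition. `log2fc` is
#' `mean(treatment) - mean(reference)` (a log2 fold change, since values
#' are on the log2 scale). The default statistic, `"moderated_t"`,
#' shrinks the gene-wise pooled variances toward their mean with a fixed
#' prior weight `d0` — the light-weight analogue of the moderated
#' statistics standard for microarray designs with few replicates, where
#' the per-gene Welch test (`"welch_t"`, also available) is badly
#' underpowered. BH adjustment is applied over all genes within the
#' contrast.
#'
#' Genes with identical values in both groups (zero difference, zero
#' variance) get `log2fc = 0, p = 1`; a nonzero difference with zero
#' within-group variance gets `p = 0`.
#'
#' @param study An `ExpressionStudy`.
#' @param treatment,reference Condition labels; each must have >= 2
#'   samples.
#' @param method `"moderated_t"` (default) or `"welch_t"`.
#' @param d0 Prior degrees of freedom for the moderated statistic.
#' @return A `ContrastTable`: data frame with columns `gene_id`,
#'   `biotype`, `log2fc`, `p`, `p_adj`, one row per gene, plus a
#'   `"contrast"` attribute `"<treatment>_vs_<reference>"`.
#' @export
contrast <- function(study, treatment, reference,
                     method = c("moderated_t", "welch_t"), d0 = 4) {
  stopifnot(inherits(study, "ExpressionStudy"))
  method <- match.arg(method)
  it <- which(study$condition == treatment)
  ir <- which(study$condition == reference)
  if (length(it) < 2)
    stop("condition '", treatment, "' has fewer than 2 samples")
  if (length(ir) < 2)
    stop("condition '", reference, "' has fewer than 2 samples")
  xt <- study$values[, it, drop = FALSE]
  xr <- study$values[, ir, drop = FALSE]
  n1 <- length(it); n2 <- length(ir)
  m1 <- rowMeans(xt); m2 <- rowMeans(xr)
  v1 <- rowSums((xt - m1)^2) / (n1 - 1)
  v2 <- rowSums((xr - m2)^2) / (n2 - 1)
  diff <- m1 - m2

  if (method == "welch_t") {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    tt <- diff / sqrt(se2)
    p <- 2 * pt(-abs(tt), df)
  } else {
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
    s2_0 <- mean(sp2)
    s2_post <- (d0 * s2_0 + df * sp2) / (d0 + df)
    tt <- diff / sqrt(s2_post * (1 / n1 + 1 / n2))
    p <- 2 * pt(-abs(tt), df + d0)
  }
  # degenerate genes: zero within-group variance
  zero <- !is.finite(p)
  p[zero] <- ifelse(abs(diff[zero]) > 0, 0, 1)

  out <- data.frame(gene_id = rownames(study$values),
                    biotype = unname(study$biotype),
                    log2fc = unname(diff),
                    p = unname(p),
                    p_adj = bh_adjust(unname(p)),
                    stringsAsFactors = FALSE)
  attr(out, "contrast") <- paste0(treatment, "_vs_", reference)
  class(out) <- c("ContrastTable", "data.frame")
  out
}

#' Reversal-based ERAR gene filter
#'
#' A gene is estrogen-receptor agitation-related (ERAR) when it is
#' significantly differentially expressed in *both* contrasts — agonist
#' versus vehicle (`c1`, e.g. E2 vs ethanol) and agonist-plus-antagonist
#' versus agonist (`c2`, e.g. E2+ICI vs E2) — with *opposite* fold-change
#' signs, i.e. the antagonist reverses the agonist response. Significance
#' means `|log2fc| > log2(fc_threshold)` and BH-adjusted `p < alpha` in
#' each contrast. Direction (`up`/`down`) is taken from `c1`.
#'
#' @param c1 `ContrastTable` for the agonist-vs-vehicle comparison.
#' @param c2 `ContrastTable` for the reversal comparison, over the same
#'   gene universe.
#' @param fc_threshold Linear-scale fold-change threshold (>= 1);
#'   default 2, i.e. `|log2fc| > 1`.
#' @param alpha Adjusted-p threshold; default 0.01.
#' @return An `ERARSet`: data frame with columns `gene_id`, `biotype`,
#'   `direction`, `log2fc_c1`, `p_adj_c1`, `log2fc_c2`, `p_adj_c2`.
#' @export
erar_filter <- function(c1, c2, fc_threshold = 2, alpha = 0.01) {
  stopifnot(inherits(c1, "ContrastTable"), inherits(c2, "ContrastTable"))
  if (!is.numeric(fc_threshold) || fc_threshold < 1)
    stop("'fc_threshold' must be >= 1")
  if (!identical(c1$gene_id, c2$gene_id))
    stop("contrast tables cover different gene universes")
  lfc <- log2(fc_threshold)
  sig1 <- abs(c1$log2fc) > lfc & c1$p_adj < alpha
  sig2 <- abs(c2$log2fc) > lfc & c2$p_adj < alpha
  reversed <- sign(c1$log2fc) == -sign(c2$log2fc) & c1$log2fc != 0
  keep <- sig1 & sig2 & reversed
  out <- data.frame(gene_id = c1$gene_id[keep],
                    biotype = c1$biotype[keep],
                    direction = ifelse(c1$log2fc[keep] > 0, "up", "down"),
                    log2fc_c1 = c1$log2fc[keep],
                    p_adj_c1 = c1$p_adj[keep],
                    log2fc_c2 = c2$log2fc[keep],
                    p_adj_c2 = c2$p_adj[keep],
                    stringsAsFactors = FALSE)
  class(out) <- c("ERARSet", "data.frame")
  out
}

#' Write a contrast table or ERAR set to TSV
#'
#' @param x A `ContrastTable` or `ERARSet`.
#' @param path Output path.
#' @return Invisibly, `x`.
#' @export
write_table_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(x)
}
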