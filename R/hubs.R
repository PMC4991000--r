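#' Upper-tail cumulative hypergeometric probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the chance of drawing at
#' least `k` annotated genes when `n` genes are sampled without
#' replacement from a universe of `N` containing `K` annotated members.
#' Computed via `phyper` (log-space internals), vectorised over `k`.
#'
#' @param k Observed overlap, `0 <= k <= min(K, n)`.
#' @param K Annotated genes in the universe (term size).
#' @param n Sample size (e.g. hub neighbour count).
#' @param N Universe size; `K, n <= N`.
#' @return Probability in \[0, 1\].
#' @export
hypergeom_tail <- function(k, K, n, N) {
  if (any(K > N) || any(n > N))
    stop("'K' and 'n' must not exceed the universe size 'N'")
  if (any(k < 0) || any(k > pmin(K, n)))
    stop("'k' must lie in [0, min(K, n)]")
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Extract lncRNA hubs from a CNC network
#'
#' A hub is a lncRNA node adjacent to at least `min_neighbours`
#' protein-coding genes. Only coding neighbours (CN edges) count toward
#' the threshold and enter the neighbour set — lncRNA-lncRNA edges carry
#' no functional annotation.
#'
#' @param net A `CNCNetwork`.
#' @param min_neighbours Minimum coding-neighbour count; default 10.
#' @return Named list, one element per hub lncRNA, each a character
#'   vector of coding neighbour gene ids. Empty list when no lncRNA
#'   qualifies.
#' @export
extract_hubs <- function(net, min_neighbours = 10) {
  stopifnot(inherits(net, "CNCNetwork"))
  cn <- net$edges[net$edges$class == "CN", , drop = FALSE]
  if (!nrow(cn)) return(setNames(list(), character(0)))
  bt <- setNames(net$nodes$biotype, net$nodes$gene_id)
  lnc <- ifelse(bt[cn$gene_a] == "lncRNA", cn$gene_a, cn$gene_b)
  cod <- ifelse(bt[cn$gene_a] == "lncRNA", cn$gene_b, cn$gene_a)
  by_hub <- split(cod, lnc)
  by_hub[lengths(by_hub) >= min_neighbours]
}

#' Gene-set enrichment of one hub's neighbours
#'
#' Tests each term of a gene-set collection for over-representation among
#' the coding neighbours of a hub lncRNA, with the upper-tail cumulative
#' hypergeometric test ([hypergeom_tail()]). Term membership and the
#' neighbour count are restricted to the stated universe; every neighbour
#' must belong to the universe. No multiple-testing correction is applied
#' across terms by default (set `adjust = TRUE` for BH). Terms whose
#' within-universe size falls outside `[min_term_size, max_term_size]`
#' are skipped.
#'
#' @param hub Hub lncRNA gene id (bookkeeping only).
#' @param neighbours Character vector of coding neighbour gene ids.
#' @param sets A `GeneSetCollection`.
#' @param universe Character vector of background gene ids.
#' @param alpha Enrichment p threshold; default 0.01.
#' @param min_term_size,max_term_size Within-universe term-size bounds.
#' @param adjust Apply BH across terms before thresholding.
#' @return A `HubSubnetwork` (list with `hub`, `neighbours`,
#'   `enrichment` data frame sorted ascending by p) or `NULL` when no
#'   term passes — such hubs are dropped from reports.
#' @export
annotate_hub <- function(hub, neighbours, sets, universe, alpha = 0.01,
                         min_term_size = 5, max_term_size = 2000,
                         adjust = FALSE) {
  miss <- setdiff(neighbours, universe)
  if (length(miss))
    stop("neighbour(s) absent from universe: ",
         paste(head(miss, 5), collapse = ", "))
  N <- length(universe)
  n <- length(neighbours)
  rows <- lapply(names(sets), function(id) {
    members <- intersect(sets[[id]]$genes, universe)
    K <- length(members)
    if (K < min_term_size || K > max_term_size) return(NULL)
    k <- length(intersect(neighbours, members))
    data.frame(term_id = id, term_name = sets[[id]]$name,
               overlap = k, term_size = K, n_neighbours = n,
               universe_size = N,
               p = hypergeom_tail(k, K, n, N),
               stringsAsFactors = FALSE)
  })
  enr <- do.call(rbind, rows)
  if (is.null(enr)) return(NULL)
  if (adjust) enr$p_adj <- bh_adjust(enr$p)
  crit <- if (adjust) enr$p_adj else enr$p
  enr <- enr[crit < alpha, , drop = FALSE]
  if (!nrow(enr)) return(NULL)
  enr <- enr[order(enr$p), , drop = FALSE]
  rownames(enr) <- NULL
  structure(list(hub = hub, neighbours = neighbours, enrichment = enr),
            class = "HubSubnetwork")
}

#' Default enrichment universe
#'
#' All coding genes of the study that belong to at least one gene set —
#' the natural background when annotations only exist for a subset of
#' the array.
#'
#' @param study An `ExpressionStudy`.
#' @param sets A `GeneSetCollection`, or `NULL` to use all coding genes.
#' @return Character vector of gene ids.
#' @export
enrichment_universe <- function(study, sets = NULL) {
  coding <- names(study$biotype)[study$biotype == "coding"]
  if (is.null(sets)) return(coding)
  annotated <- unique(unlist(lapply(sets, `[[`, "genes"),
                             use.names = FALSE))
  intersect(coding, annotated)
}

#' Hub-based lncRNA function assignment
#'
#' Runs [extract_hubs()] and [annotate_hub()] over a whole network:
#' each lncRNA with at least `min_neighbours` coding neighbours and at
#' least one enriched term receives those terms as predicted functions
#' (guilt by association). Neighbours outside the universe are excluded
#' before testing.
#'
#' @param net A `CNCNetwork`.
#' @param sets A `GeneSetCollection`.
#' @param universe Background gene ids; when `NULL` the union of all
#'   gene-set members restricted to coding network-study genes must be
#'   supplied via `study`.
#' @param study Optional `ExpressionStudy` used to derive the default
#'   universe (see [enrichment_universe()]).
#' @param min_neighbours Minimum coding neighbours per hub; default 10.
#' @param alpha Enrichment p threshold; default 0.01.
#' @param ... Passed on to [annotate_hub()].
#' @return List of `HubSubnetwork` objects (hubs with >= 1 enriched
#'   term), named by hub id.
#' @export
hub_report <- function(net, sets, universe = NULL, study = NULL,
                       min_neighbours = 10, alpha = 0.01, ...) {
  if (is.null(universe)) {
    if (is.null(study))
      stop("supply 'universe' or 'study' to derive it")
    universe <- enrichment_universe(study, sets)
  }
  hubs <- extract_hubs(net, min_neighbours)
  out <- list()
  for (h in names(hubs)) {
    nb <- intersect(hubs[[h]], universe)
    if (length(nb) < min_neighbours) next
    ann <- annotate_hub(h, nb, sets, universe, alpha = alpha, ...)
    if (!is.null(ann)) out[[h]] <- ann
  }
  out
}

#' Frequency of predicted functions across hubs
#'
#' @param hubs List of `HubSubnetwork` objects (e.g. from
#'   [hub_report()]).
#' @return Named integer vector: term id -> number of hubs carrying the
#'   term, sorted decreasing.
#' @export
function_frequency <- function(hubs) {
  terms <- unlist(lapply(hubs, function(h) unique(h$enrichment$term_id)),
                  use.names = FALSE)
  if (!length(terms)) return(setNames(integer(0), character(0)))
  tab <- table(terms)
  sort(setNames(as.integer(tab), names(tab)), decreasing = TRUE)
}

#' Write a hub report to TSV
#'
#' One row per (hub, enriched term):
#' `hub_lncRNA, n_neighbours, term_id, term_name, overlap, term_size, p`.
#'
#' @param hubs List of `HubSubnetwork` objects.
#' @param path Output path.
#' @return Invisibly, the flattened data frame.
#' @export
write_hub_report <- function(hubs, path) {
  rows <- lapply(hubs, function(h) {
    data.frame(hub_lncRNA = h$hub,
               n_neighbours = length(h$neighbours),
               h$enrichment[, c("term_id", "term_name", "overlap",
                                "term_size", "p")],
               stringsAsFactors = FALSE)
  })
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(hub_lncRNA = character(0), n_neighbours = integer(0),
               term_id = character(0), term_name = character(0),
               overlap = integer(0), term_size = integer(0),
               p = numeric(0))
  rownames(df) <- NULL
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
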