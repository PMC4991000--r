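test_that("pearson_matrix matches the definitional formula", {
  st <- random_study(10, 8, seed = 31)
  r <- pearson_matrix(st)
  expect_true(isSymmetric(r))
  expect_equal(unname(diag(r)), rep(1, 10))
  for (i in 1:9) for (j in (i + 1):10)
    expect_equal(r[i, j],
                 oracle_pcc(st$values[i, ], st$values[j, ]),
                 tolerance = 1e-12)

  # duplicated gene and negated gene hit the bounds exactly
  x <- st$values[1:3, ]
  x[2, ] <- x[1, ]
  x[3, ] <- -x[1, ]
  r2 <- pearson_matrix(make_study(x))
  expect_equal(r2[1, 2], 1)
  expect_equal(r2[1, 3], -1)

  # zero-variance gene refused by name
  x[3, ] <- 5
  expect_error(pearson_matrix(make_study(x)), rownames(x)[3])
  expect_error(pearson_matrix(random_study(5, 3, seed = 1)),
               ">= 4 samples")
})

test_that("Fisher z p-values agree with the closed form and are monotone", {
  expect_equal(fisher_corr_pvalue(0, 10), 1)
  expect_equal(fisher_corr_pvalue(0.5, 30),
               oracle_fisher_p(0.5, 30), tolerance = 1e-10)
  expect_equal(fisher_corr_pvalue(1, 10), 0)
  expect_equal(fisher_corr_pvalue(-1, 10), 0)
  expect_error(fisher_corr_pvalue(0.5, 3), "n > 3")

  # strictly decreasing in |r| at fixed n, and in n at fixed r != 0
  rs <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(diff(fisher_corr_pvalue(rs, 20)) < 0))
  ns <- c(5, 10, 20, 40, 80)
  expect_true(all(diff(fisher_corr_pvalue(0.4, ns)) < 0))

  # the exact-t alternative agrees with cor.test
  ct <- cor.test(rnorm(12), rnorm(12))
  expect_equal(exact_t_corr_pvalue(unname(ct$estimate), 12), ct$p.value,
               tolerance = 1e-10)
})

test_that("percentile edge mask equals a per-row sort oracle", {
  set.seed(17)
  st <- random_study(12, 9, seed = 17)
  r <- pearson_matrix(st)
  m <- percentile_edge_mask(r, 0.1)
  for (g in 1:12) {
    vals <- r[g, -g]
    lo <- oracle_quantile7(vals, 0.1)
    hi <- oracle_quantile7(vals, 0.9)
    expect_identical(unname(m[g, -g]), unname(vals >= hi | vals <= lo))
  }
  expect_false(any(diag(m)))

  # degenerate: all off-diagonal correlations equal -> all flagged
  rconst <- matrix(0.5, 3, 3); diag(rconst) <- 1
  dimnames(rconst) <- list(letters[1:3], letters[1:3])
  mm <- percentile_edge_mask(rconst, 0.05)
  expect_true(all(mm[upper.tri(mm) | lower.tri(mm)]))

  expect_error(percentile_edge_mask(r, 0.5), "q")
  expect_error(percentile_edge_mask(r, 0), "q")
})

test_that("build_network matches an independently coded triple-loop reference", {
  for (seed in c(5, 6)) {
    set.seed(seed)
    # small instance with induced correlation so some edges survive
    ns <- 12
    f <- rnorm(ns)
    x <- rbind(t(sapply(1:6, function(i) 0.97 * f + 0.2 * rnorm(ns))),
               matrix(rnorm(9 * ns), nrow = 9))
    rownames(x) <- sprintf("g%02d", 1:15)
    colnames(x) <- sprintf("s%02d", 1:ns)
    st <- make_study(x, biotype = setNames(
      rep(c("lncRNA", "coding"), c(3, 12)), rownames(x)))
    net <- build_network(st, pcc_cutoff = 0.8, alpha = 0.05, q = 0.25)
    got <- sort(paste(pmin(net$edges$gene_a, net$edges$gene_b),
                      pmax(net$edges$gene_a, net$edges$gene_b),
                      sep = "|"))
    expect_identical(got, oracle_network_edges(st, 0.8, 0.05, 0.25))
  }
})

test_that("network filtering is monotone under stricter thresholds", {
  m <- generate_module_study(generator_config(
    n_coding = 150, n_lnc = 15, n_modules = 2, seed = 12))
  st <- variance_filter(m$study, 0.75)
  key <- function(net) paste(net$edges$gene_a, net$edges$gene_b)
  base <- build_network(st, pcc_cutoff = 0.85, alpha = 0.05, q = 0.1)
  expect_true(all(key(build_network(st, 0.93, 0.05, q = 0.1)) %in%
                    key(base)))
  expect_true(all(key(build_network(st, 0.85, 0.01, q = 0.1)) %in%
                    key(base)))
  expect_true(all(key(build_network(st, 0.85, 0.05, q = 0.02)) %in%
                    key(base)))
  # 'either' endpoint rule is a supergraph of 'both'
  expect_true(all(key(base) %in%
                    key(build_network(st, 0.85, 0.05, q = 0.1,
                                      endpoint_rule = "either"))))
})

test_that("build_network is invariant to gene and sample permutations", {
  m <- generate_module_study(generator_config(
    n_coding = 80, n_lnc = 10, n_modules = 1, seed = 23))
  st <- m$study
  net1 <- build_network(st, 0.8, 0.05, 0.1)
  set.seed(1)
  pg <- sample(nrow(st$values)); psamp <- sample(ncol(st$values))
  st2 <- expression_study(st$values[pg, psamp],
                          st$condition[psamp], st$biotype[pg])
  net2 <- build_network(st2, 0.8, 0.05, 0.1)
  key <- function(net) sort(paste(pmin(net$edges$gene_a, net$edges$gene_b),
                                  pmax(net$edges$gene_a, net$edges$gene_b)))
  expect_identical(key(net1), key(net2))
  expect_setequal(net1$nodes$gene_id, net2$nodes$gene_id)
})

test_that("white-noise studies produce (near-)empty networks", {
  edges <- vapply(1:10, function(s) {
    nrow(build_network(random_study(200, 20, seed = 100 + s,
                                    n_lnc = 20))$edges)
  }, numeric(1))
  expect_true(all(edges <= 2))
})

test_that("network summary counts agree with an edge-list recount", {
  # hand-built 5-node graph: 3 coding, 2 lncRNA; 2 CC + 2 CN + 1 NN
  edges <- data.frame(
    gene_a = c("c1", "c1", "c1", "c2", "l1"),
    gene_b = c("c2", "c3", "l1", "l2", "l2"),
    pcc = 0.95, p_raw = 1e-6, p_bonferroni = 1e-3,
    class = c("CC", "CC", "CN", "CN", "NN"),
    stringsAsFactors = FALSE)
  nodes <- data.frame(gene_id = c("c1", "c2", "c3", "l1", "l2"),
                      biotype = c("coding", "coding", "coding",
                                  "lncRNA", "lncRNA"),
                      degree = c(3, 2, 1, 2, 2),
                      stringsAsFactors = FALSE)
  net <- structure(list(nodes = nodes, edges = edges,
                        n_tested_pairs = 10), class = "CNCNetwork")
  s <- network_summary(net)
  expect_equal(s[c("n_coding", "n_lncRNA", "n_CC", "n_CN", "n_NN")],
               list(n_coding = 3, n_lncRNA = 2, n_CC = 2, n_CN = 2,
                    n_NN = 1))
  expect_equal(s$n_edges, s$n_CC + s$n_CN + s$n_NN)

  # recount on a generated network; class partition exhaustive
  m <- generate_module_study(generator_config(
    n_coding = 100, n_lnc = 10, n_modules = 1, seed = 2))
  net2 <- build_network(m$study, 0.8, 0.05, 0.1)
  s2 <- network_summary(net2)
  bt <- setNames(net2$nodes$biotype, net2$nodes$gene_id)
  ncn <- sum((bt[net2$edges$gene_a] == "lncRNA") !=
               (bt[net2$edges$gene_b] == "lncRNA"))
  expect_equal(s2$n_CN, ncn)
  expect_equal(s2$n_edges, s2$n_CC + s2$n_CN + s2$n_NN)
})

test_that("empty networks summarise to zero and export round-trips", {
  st <- random_study(50, 10, seed = 77, n_lnc = 5)
  net <- build_network(st)  # defaults on white noise: empty
  s <- network_summary(net)
  expect_equal(s$n_edges, 0)
  expect_equal(s$n_coding + s$n_lncRNA, 0)

  m <- generate_module_study(generator_config(
    n_coding = 80, n_lnc = 10, n_modules = 1, seed = 3))
  net2 <- build_network(m$study, 0.8, 0.05, 0.1)
  d <- withr::local_tempdir()
  write_network(net2, file.path(d, "e.tsv"), file.path(d, "n.tsv"),
                graphml_path = file.path(d, "g.graphml"))
  eb <- read.delim(file.path(d, "e.tsv"))
  expect_equal(nrow(eb), nrow(net2$edges))
  expect_true(file.exists(file.path(d, "g.graphml")))
  g <- as_igraph(net2)
  expect_equal(igraph::gsize(g), nrow(net2$edges))
})
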