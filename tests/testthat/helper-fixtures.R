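# Small in-code fixtures shared across test files.

# A study built from an explicit matrix; biotype defaults to coding,
# condition to a single label.
make_study <- function(values, condition = NULL, biotype = NULL) {
  if (is.null(condition))
    condition <- setNames(rep("c1", ncol(values)), colnames(values))
  if (is.null(biotype))
    biotype <- setNames(rep("coding", nrow(values)), rownames(values))
  expression_study(values, condition, biotype)
}

# Random study: ng genes x ns samples of white noise.
random_study <- function(ng, ns, seed, n_lnc = 0, sd = 1) {
  set.seed(seed)
  genes <- c(sprintf("g%03d", seq_len(ng - n_lnc)),
             if (n_lnc > 0) sprintf("l%03d", seq_len(n_lnc)))
  x <- matrix(rnorm(ng * ns, mean = 7, sd = sd), nrow = ng,
              dimnames = list(genes, sprintf("s%02d", seq_len(ns))))
  make_study(x, biotype = setNames(
    rep(c("coding", "lncRNA"), c(ng - n_lnc, n_lnc)), genes))
}

# Two-condition study from two per-gene sample blocks.
two_group_study <- function(xa, xb, cond = c("E2", "ethanol")) {
  stopifnot(nrow(xa) == nrow(xb))
  colnames(xa) <- paste0("a", seq_len(ncol(xa)))
  colnames(xb) <- paste0("b", seq_len(ncol(xb)))
  x <- cbind(xa, xb)
  make_study(x, condition = setNames(
    rep(cond, c(ncol(xa), ncol(xb))), colnames(x)))
}

# Tiny three-gene GMT written to a temp file.
write_tiny_gmt <- function(path) {
  writeLines(c("T1\tfirst term\tg1\tg2\tg3",
               "T2\tsecond term\tg2\tg4"), path)
  path
}
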