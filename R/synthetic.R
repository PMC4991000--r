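# Synthetic-data generators with planted ground truth. Every generator
# returns a truth manifest so downstream recovery can be scored exactly.

#' Generator configuration
#'
#' Bundles all knobs of the synthetic generators with defaults sized so
#' the full pipeline runs in well under a minute while mirroring the
#' study design the analysis assumes: a three-condition cell-line
#' experiment (vehicle / agonist / agonist+antagonist) with a planted
#' "up-then-reversed" gene subset, latent-factor co-expression modules
#' with lncRNA hubs, gene sets enriched in module members, and patient
#' cohorts whose hazard depends on a few informative lncRNAs.
#'
#' @param n_coding,n_lnc Number of coding / lncRNA genes (1000 / 100).
#' @param n_per_condition Replicates per condition (4).
#' @param erar_n,erar_delta,erar_frac_up Planted reversal genes: count
#'   (30), absolute log2 shift in the agonist condition (3), fraction
#'   shifted upward (0.5).
#' @param background_sd Residual expression noise SD, log2 units (0.3).
#' @param n_network_samples Samples for the co-expression study (30).
#' @param module_n_coding,module_n_hubs Coding members and lncRNA hubs
#'   per planted module (15 / 1).
#' @param n_modules Number of planted modules (3).
#' @param loading Latent-factor loading of module members (0.97).
#' @param module_noise_sd Residual noise SD of module members; the
#'   default `NULL` means `sqrt(1 - loading^2)` (unit member variance),
#'   giving expected within-module pairwise correlation `loading^2`,
#'   about 0.94 at the default loading — just above the 0.93 edge
#'   cutoff. Smaller values raise the within-module correlation to
#'   `loading^2 / (loading^2 + module_noise_sd^2)`.
#' @param n_terms,term_size,overlap_fraction Gene-set collection: number
#'   of terms (200), genes per term (20), fraction of each planted term
#'   occupied by one module's coding members (0.75).
#' @param n_patients Cohort size (164).
#' @param n_informative Number of hazard-linked features (5).
#' @param n_candidates Total candidate features in the cohort (33).
#' @param hazard_ratio Hazard ratio between latent risk groups (3).
#' @param censoring_fraction Target censoring fraction (0.3).
#' @param baseline_hazard Exponential baseline hazard, events per month
#'   (0.01).
#' @param feature_delta Mean expression separation of informative
#'   features between risk groups, SD units (1.5).
#' @param seed RNG seed (1).
#' @return A validated `GeneratorConfig` list.
#' @export
generator_config <- function(n_coding = 1000, n_lnc = 100,
                             n_per_condition = 4,
                             erar_n = 30, erar_delta = 3,
                             erar_frac_up = 0.5,
                             background_sd = 0.3,
                             n_network_samples = 30,
                             module_n_coding = 15, module_n_hubs = 1,
                             n_modules = 3, loading = 0.97,
                             module_noise_sd = NULL,
                             n_terms = 200, term_size = 20,
                             overlap_fraction = 0.75,
                             n_patients = 164, n_informative = 5,
                             n_candidates = 33, hazard_ratio = 3,
                             censoring_fraction = 0.3,
                             baseline_hazard = 0.01,
                             feature_delta = 1.5,
                             seed = 1) {
  cfg <- as.list(environment())
  counts <- c("n_coding", "n_lnc", "n_per_condition", "erar_n",
              "n_network_samples", "module_n_coding", "module_n_hubs",
              "n_modules", "n_terms", "term_size", "n_patients",
              "n_informative", "n_candidates")
  for (nm in counts)
    if (cfg[[nm]] < 0 || cfg[[nm]] != round(cfg[[nm]]))
      stop("'", nm, "' must be a nonnegative integer")
  if (loading < 0 || loading >= 1) stop("'loading' must be in [0, 1)")
  if (is.null(module_noise_sd))
    cfg$module_noise_sd <- sqrt(1 - loading^2)
  else if (module_noise_sd <= 0)
    stop("'module_noise_sd' must be positive")
  if (censoring_fraction < 0 || censoring_fraction >= 1)
    stop("'censoring_fraction' must be in [0, 1)")
  if (erar_frac_up < 0 || erar_frac_up > 1)
    stop("'erar_frac_up' must be in [0, 1]")
  if (n_informative > n_candidates)
    stop("'n_informative' exceeds 'n_candidates'")
  structure(cfg, class = "GeneratorConfig")
}

gene_ids <- function(cfg) {
  c(sprintf("PC%04d", seq_len(cfg$n_coding)),
    sprintf("LNC%03d", seq_len(cfg$n_lnc)))
}

gene_biotypes <- function(cfg) {
  setNames(rep(c("coding", "lncRNA"), c(cfg$n_coding, cfg$n_lnc)),
           gene_ids(cfg))
}

#' Generate a three-condition expression study with planted ERAR genes
#'
#' Background expression is gene-wise Normal with mean drawn uniformly
#' from 5-10 log2 units and SD `background_sd`, identical across the
#' three conditions (ethanol, E2, E2_ICI). Planted ERAR genes shift by
#' +/- `erar_delta` in the E2 samples and return to baseline under
#' E2_ICI — the agonist response reversed by the antagonist. The planted
#' set is drawn from both biotypes.
#'
#' @param cfg A [generator_config()].
#' @return List with `study` (an `ExpressionStudy`) and `truth` (list
#'   with `erar_genes`, `erar_direction`).
#' @export
generate_three_condition_study <- function(cfg = generator_config()) {
  stopifnot(inherits(cfg, "GeneratorConfig"))
  with_seed(cfg$seed, {
    genes <- gene_ids(cfg)
    bt <- gene_biotypes(cfg)
    nrep <- cfg$n_per_condition
    conds <- rep(c("ethanol", "E2", "E2_ICI"), each = nrep)
    samples <- paste0(conds, "_", rep(seq_len(nrep), 3))
    mu <- runif(length(genes), 5, 10)
    x <- matrix(rnorm(length(genes) * length(samples), mean = mu,
                      sd = cfg$background_sd),
                nrow = length(genes),
                dimnames = list(genes, samples))
    erar <- if (cfg$erar_n > 0) sort(sample(genes, cfg$erar_n))
            else character(0)
    n_up <- round(cfg$erar_frac_up * length(erar))
    dir <- setNames(rep(c("up", "down"),
                        c(n_up, length(erar) - n_up)), erar)
    shift <- ifelse(dir == "up", cfg$erar_delta, -cfg$erar_delta)
    x[erar, conds == "E2"] <- x[erar, conds == "E2"] + shift
    study <- expression_study(x, setNames(conds, samples), bt)
    list(study = study,
         truth = list(erar_genes = erar, erar_direction = dir))
  })
}

#' Generate a co-expression study with planted modules and gene sets
#'
#' Each module has a per-sample latent factor `f ~ N(0,1)`; member genes
#' (its coding members and hub lncRNAs) follow
#' `loading * f + sqrt(1 - loading^2) * noise` (plus a gene-specific
#' baseline), so the expected within-module pairwise Pearson correlation
#' is `loading^2`. Background genes are independent Normal noise with SD
#' `background_sd`, which also keeps module genes above the variance
#' filter. The gene-set collection plants one term per module whose
#' members include `overlap_fraction * term_size` of that module's
#' coding genes; all other terms are filled with random non-module
#' coding genes.
#'
#' @param cfg A [generator_config()].
#' @return List with `study`, `sets` (a `GeneSetCollection`) and `truth`
#'   (list with `modules` — per module, `coding`, `hubs` and `term` —
#'   and `hub_ids`).
#' @export
generate_module_study <- function(cfg = generator_config()) {
  stopifnot(inherits(cfg, "GeneratorConfig"))
  need_c <- cfg$n_modules * cfg$module_n_coding
  need_l <- cfg$n_modules * cfg$module_n_hubs
  if (need_c > cfg$n_coding || need_l > cfg$n_lnc)
    stop("module sizes exceed the gene pool")
  with_seed(cfg$seed, {
    genes <- gene_ids(cfg)
    bt <- gene_biotypes(cfg)
    ns <- cfg$n_network_samples
    samples <- sprintf("S%02d", seq_len(ns))
    mu <- runif(length(genes), 5, 10)
    x <- matrix(rnorm(length(genes) * ns, mean = mu,
                      sd = cfg$background_sd),
                nrow = length(genes), dimnames = list(genes, samples))
    coding_pool <- genes[bt == "coding"]
    lnc_pool <- genes[bt == "lncRNA"]
    mod_coding <- split(sample(coding_pool, need_c),
                        rep(seq_len(cfg$n_modules),
                            each = cfg$module_n_coding))
    mod_hubs <- split(sample(lnc_pool, need_l),
                      rep(seq_len(cfg$n_modules),
                          each = cfg$module_n_hubs))
    lam <- cfg$loading
    nsd <- cfg$module_noise_sd
    for (m in seq_len(cfg$n_modules)) {
      f <- rnorm(ns)
      members <- c(mod_coding[[m]], mod_hubs[[m]])
      sig <- t(vapply(members, function(g) {
        mu[match(g, genes)] + lam * f + nsd * rnorm(ns)
      }, numeric(ns)))
      x[members, ] <- sig
    }
    # gene sets: one planted term per module, the rest random
    nonmod <- setdiff(coding_pool, unlist(mod_coding))
    if (length(nonmod) < cfg$term_size)
      stop("non-module coding pool (", length(nonmod),
           ") smaller than 'term_size'; enlarge 'n_coding'")
    n_overlap <- round(cfg$overlap_fraction * cfg$term_size)
    n_overlap <- min(n_overlap, cfg$module_n_coding)
    sets <- vector("list", cfg$n_terms)
    ids <- sprintf("T%04d", seq_len(cfg$n_terms))
    planted_term <- character(cfg$n_modules)
    for (i in seq_len(cfg$n_terms)) {
      if (i <= cfg$n_modules) {
        members <- c(sample(mod_coding[[i]], n_overlap),
                     sample(nonmod, cfg$term_size - n_overlap))
        planted_term[i] <- ids[i]
      } else {
        members <- sample(nonmod, cfg$term_size)
      }
      sets[[i]] <- list(name = paste0("synthetic process ", i),
                       genes = sort(members))
    }
    sets <- structure(setNames(sets, ids), class = "GeneSetCollection")
    study <- expression_study(
      x, setNames(rep("network", ns), samples), bt)
    modules <- lapply(seq_len(cfg$n_modules), function(m) {
      list(coding = mod_coding[[m]], hubs = mod_hubs[[m]],
           term = planted_term[m])
    })
    list(study = study, sets = sets,
         truth = list(modules = modules,
                      hub_ids = sort(unlist(mod_hubs))))
  })
}

# Censoring horizon c for uniform censoring U(0, c) against a balanced
# two-group exponential mixture with rates h0 and h0*HR: solves
# P(censored) = target in closed form + uniroot.
censoring_horizon <- function(h0, hr, target) {
  if (target <= 0) return(Inf)
  pc <- function(cc) {
    rates <- c(h0, h0 * hr)
    mean(vapply(rates, function(h) (1 - exp(-h * cc)) / (h * cc),
                numeric(1))) - target
  }
  uniroot(pc, lower = 1e-6, upper = 1e6, tol = 1e-10)$root
}

#' Generate a survival cohort with planted prognostic features
#'
#' Patients carry a balanced latent risk group; survival times are
#' exponential with hazard `baseline_hazard * hazard_ratio^group`, with
#' independent uniform censoring whose horizon is calibrated in closed
#' form to the requested censoring fraction. Informative features are
#' Normal with means `+/- feature_delta / 2` by risk group; the
#' remaining candidates are standard-Normal noise.
#'
#' @param cfg A [generator_config()].
#' @param feature_pool Optional character vector of candidate feature
#'   names (length >= `n_candidates`); defaults to `LNC001...`.
#' @param n_patients Override for `cfg$n_patients` (e.g. a validation
#'   cohort of different size).
#' @param informative Optional character vector fixing which features
#'   are hazard-linked — used to generate a validation cohort carrying
#'   the same prognostic genes as a discovery cohort. Default: sampled
#'   from the candidates.
#' @param seed Override for `cfg$seed`.
#' @return List with `cohort` (a `SurvivalCohort`) and `truth` (list
#'   with `risk_group` per patient and `informative` feature ids).
#' @export
generate_cohort <- function(cfg = generator_config(),
                            feature_pool = NULL,
                            n_patients = cfg$n_patients,
                            informative = NULL,
                            seed = cfg$seed) {
  stopifnot(inherits(cfg, "GeneratorConfig"))
  if (is.null(feature_pool))
    feature_pool <- sprintf("LNC%03d", seq_len(cfg$n_candidates))
  if (length(feature_pool) < cfg$n_candidates)
    stop("feature pool smaller than 'n_candidates'")
  with_seed(seed, {
    n <- n_patients
    pats <- sprintf("P%03d", seq_len(n))
    z <- sample(rep(0:1, length.out = n))
    feats <- feature_pool[seq_len(cfg$n_candidates)]
    if (is.null(informative))
      informative <- sort(sample(feats, cfg$n_informative))
    else if (!all(informative %in% feats))
      stop("'informative' features must be among the candidates")
    x <- matrix(rnorm(n * length(feats)), nrow = n,
                dimnames = list(pats, feats))
    for (g in informative)
      x[, g] <- x[, g] + ifelse(z == 1, cfg$feature_delta / 2,
                                -cfg$feature_delta / 2)
    rate <- cfg$baseline_hazard * cfg$hazard_ratio^z
    t_event <- rexp(n, rate)
    if (cfg$censoring_fraction > 0) {
      cc <- censoring_horizon(cfg$baseline_hazard, cfg$hazard_ratio,
                              cfg$censoring_fraction)
      t_cens <- runif(n, 0, cc)
    } else t_cens <- rep(Inf, n)
    time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)
    cohort <- survival_cohort(time, event, x)
    list(cohort = cohort,
         truth = list(risk_group = setNames(z, pats),
                      informative = informative))
  })
}

#' Write a synthetic truth manifest as JSON
#'
#' @param truth A truth list from any generator.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_manifest <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
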