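# Survival stage: RF-RFE feature selection, k-means stratification,
# Kaplan-Meier curves and the log-rank test.

# Run `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

# Stratified fold assignment: each class is split as evenly as possible.
stratified_folds <- function(label, n_folds) {
  fold <- integer(length(label))
  for (cl in unique(label)) {
    idx <- sample(which(label == cl))
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

#' Random-forest recursive feature elimination
#'
#' Backward feature selection wrapped around a random-forest classifier,
#' following the resampling-outside-the-elimination scheme: within each
#' resample (repeated stratified k-fold), a forest is fit on the training
#' part, features are ranked by out-of-bag permutation importance, the
#' least important is dropped, and the process repeats down to a single
#' feature; held-out accuracy is recorded at every subset size. The
#' selected size maximises mean held-out accuracy (ties go to the smaller
#' size), and the selected features are those most frequently surviving
#' at that size across resamples.
#'
#' @param cohort A `SurvivalCohort` whose feature matrix holds the
#'   candidate genes.
#' @param label Binary outcome per patient (0/1 vector or factor with two
#'   levels), e.g. the event indicator. Both classes must be present.
#' @param n_folds Folds per repeat (default 5); must not exceed the
#'   smaller class size.
#' @param n_repeats Repeats of the k-fold split (default 10).
#' @param seed RNG seed; the run is deterministic given it.
#' @param num_trees Trees per forest (default 200).
#' @return An `RFEResult`: list with `accuracy_by_size` (named numeric,
#'   one entry per subset size), `selection_frequency` (per feature, how
#'   often it survived at the best size), `elimination_order` (features
#'   in average removal order, first = weakest), `best_size`, and
#'   `selected` (character vector of chosen features).
#' @export
rf_rfe <- function(cohort, label = cohort$event, n_folds = 5,
                   n_repeats = 10, seed = 1, num_trees = 200) {
  stopifnot(inherits(cohort, "SurvivalCohort"))
  x <- cohort$features
  feats <- colnames(x)
  p <- length(feats)
  if (p < 2) stop("RFE needs >= 2 candidate features")
  y <- factor(label)
  if (nlevels(y) != 2)
    stop("'label' must have exactly 2 classes (got ", nlevels(y), ")")
  if (n_folds > min(table(y)))
    stop("'n_folds' exceeds the smaller class size")

  with_seed(seed, {
    n_res <- n_folds * n_repeats
    acc <- matrix(NA_real_, nrow = p, ncol = n_res,
                  dimnames = list(as.character(seq_len(p)), NULL))
    surv_sets <- vector("list", n_res)   # surviving set per size
    removal_rank <- matrix(NA_real_, nrow = p, ncol = n_res,
                           dimnames = list(feats, NULL))
    res <- 0L
    for (rep_i in seq_len(n_repeats)) {
      fold <- stratified_folds(y, n_folds)
      for (f in seq_len(n_folds)) {
        res <- res + 1L
        tr <- fold != f
        current <- feats
        sets_here <- vector("list", p)
        for (size in seq(p, 1)) {
          d_tr <- data.frame(x[tr, current, drop = FALSE],
                             .y = y[tr], check.names = FALSE)
          fit <- ranger::ranger(
            dependent.variable.name = ".y", data = d_tr,
            num.trees = num_trees,
            importance = if (size > 1) "permutation" else "none",
            num.threads = 1)
          pred <- predict(fit,
                          data.frame(x[!tr, current, drop = FALSE],
                                     check.names = FALSE),
                          num.threads = 1)$predictions
          acc[size, res] <- mean(pred == y[!tr])
          sets_here[[size]] <- current
          if (size > 1) {
            imp <- fit$variable.importance[current]
            drop_f <- current[which.min(imp)]
            removal_rank[drop_f, res] <- p - size + 1
            current <- setdiff(current, drop_f)
          } else {
            removal_rank[current, res] <- p
          }
        }
        surv_sets[[res]] <- sets_here
      }
    }
    mean_acc <- rowMeans(acc)
    best_size <- which(mean_acc == max(mean_acc))[1]  # ties: smaller size
    freq <- table(factor(unlist(lapply(surv_sets, `[[`, best_size)),
                         levels = feats))
    sel_freq <- setNames(as.integer(freq) / n_res, feats)
    ord <- order(-sel_freq, match(feats, feats))
    selected <- feats[ord][seq_len(best_size)]
    structure(list(accuracy_by_size = setNames(mean_acc,
                                               as.character(seq_len(p))),
                   selection_frequency = sel_freq,
                   elimination_order = feats[order(rowMeans(removal_rank))],
                   best_size = as.integer(best_size),
                   selected = selected),
              class = "RFEResult")
  })
}

# k-means++-style farthest-point seeding: first centre uniform, each
# subsequent centre sampled proportionally to squared distance from the
# nearest existing centre.
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1), ]
  d2 <- rowSums((x - matrix(centers[1, ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(k - 1)) {
    prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[j + 1, ] <- x[sample.int(n, 1, prob = prob), ]
    dn <- rowSums((x - matrix(centers[j + 1, ], n, ncol(x),
                              byrow = TRUE))^2)
    d2 <- pmin(d2, dn)
  }
  centers
}

#' Stratify patients by k-means on selected features
#'
#' Features are z-scored per gene, then k-means is run with
#' k-means++-style seeding and `n_restarts` restarts; the solution with
#' the smallest within-cluster sum of squares wins. Deterministic given
#' `seed`.
#'
#' @param cohort A `SurvivalCohort`.
#' @param features Gene ids to cluster on (must be cohort columns).
#' @param k Number of groups; default 2.
#' @param seed RNG seed.
#' @param n_restarts Independent restarts; default 50.
#' @return Named integer vector: patient id -> group in `1..k`.
#' @export
kmeans_stratify <- function(cohort, features, k = 2, seed = 1,
                            n_restarts = 50) {
  stopifnot(inherits(cohort, "SurvivalCohort"))
  miss <- setdiff(features, colnames(cohort$features))
  if (length(miss))
    stop("feature(s) not in cohort: ", paste(miss, collapse = ", "))
  if (k < 2) stop("'k' must be >= 2")
  if (k > length(cohort$patients)) stop("'k' exceeds patient count")
  x <- scale(cohort$features[, features, drop = FALSE])
  with_seed(seed, {
    best <- NULL
    for (i in seq_len(n_restarts)) {
      fit <- suppressWarnings(
        kmeans(x, centers = kmeanspp_centers(x, k), iter.max = 100))
      if (is.null(best) || fit$tot.withinss < best$tot.withinss)
        best <- fit
    }
    setNames(as.integer(best$cluster), cohort$patients)
  })
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate for one group, via `survival::survfit`.
#' Censored subjects leave the risk set after their time; the curve is
#' non-increasing and starts at 1.
#'
#' @param time Nonnegative follow-up times.
#' @param event 0/1 event indicators.
#' @return Data frame `time, n_risk, n_event, n_censor, surv` over the
#'   distinct observed times.
#' @export
km_curve <- function(time, event) {
  if (!length(time)) stop("empty group")
  if (any(time < 0)) stop("'time' must be nonnegative")
  f <- survfit(Surv(time, event) ~ 1)
  data.frame(time = f$time, n_risk = f$n.risk, n_event = f$n.event,
             n_censor = f$n.censor, surv = f$surv)
}

#' Two-group log-rank test
#'
#' Standard log-rank comparison: at each distinct event time, observed
#' minus expected events accumulate with the hypergeometric variance;
#' the statistic is chi-squared with 1 degree of freedom. Wraps
#' `survival::survdiff`.
#'
#' @param time,event Follow-up times and 0/1 event indicators.
#' @param group Two-level grouping (vector coercible to factor); both
#'   groups non-empty.
#' @return List with `chi2` and `p`.
#' @export
logrank_test <- function(time, event, group) {
  g <- factor(group)
  if (nlevels(g) != 2) stop("log-rank test requires exactly 2 groups")
  if (sum(event) == 0) stop("no events observed; statistic undefined")
  sd <- survdiff(Surv(time, event) ~ g)
  chi2 <- unname(sd$chisq)
  list(chi2 = chi2, p = pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Stratify a cohort on a fixed feature panel and test survival
#'
#' k-means split on the given features, Kaplan-Meier curve per group,
#' log-rank comparison. The group with the higher event rate is labelled
#' `"poor"`, the other `"good"`.
#'
#' @param cohort A `SurvivalCohort`.
#' @param features Gene ids to stratify on.
#' @param k Number of groups (2 for the poor/good labelling).
#' @param seed RNG seed.
#' @param n_restarts k-means restarts.
#' @return A `StratificationResult`: list with `group_of` (patient ->
#'   group index), `prognosis_of` (group index -> "poor"/"good"),
#'   `km_curves` (list of per-group curves), `logrank_chi2`, `logrank_p`.
#' @export
stratify_and_test <- function(cohort, features, k = 2, seed = 1,
                              n_restarts = 50) {
  grp <- kmeans_stratify(cohort, features, k = k, seed = seed,
                         n_restarts = n_restarts)
  curves <- lapply(seq_len(k), function(g) {
    sel <- grp == g
    km_curve(cohort$time[sel], cohort$event[sel])
  })
  names(curves) <- paste0("group", seq_len(k))
  lr <- logrank_test(cohort$time, cohort$event, grp)
  prognosis <- rep("good", k)
  if (k == 2) {
    rate <- vapply(1:2, function(g) mean(cohort$event[grp == g]),
                   numeric(1))
    prognosis <- if (rate[1] >= rate[2]) c("poor", "good")
                 else c("good", "poor")
  }
  structure(list(group_of = grp,
                 prognosis_of = setNames(prognosis, seq_len(k)),
                 km_curves = curves,
                 logrank_chi2 = lr$chi2,
                 logrank_p = lr$p),
            class = "StratificationResult")
}

#' Full prognostic stage
#'
#' Chains [rf_rfe()] (feature selection against a binary outcome label)
#' into [stratify_and_test()] (k-means split on the selected panel,
#' Kaplan-Meier curves, log-rank test).
#'
#' @param cohort A `SurvivalCohort` of candidate lncRNA expression.
#' @param label Binary outcome for the RFE classifier; defaults to the
#'   event indicator.
#' @param k Number of patient groups; default 2.
#' @param seed RNG seed governing the whole stage.
#' @param n_folds,n_repeats,num_trees RFE resampling controls.
#' @param n_restarts k-means restarts.
#' @return List with elements `rfe` (an `RFEResult`) and
#'   `stratification` (a `StratificationResult`).
#' @export
prognostic_pipeline <- function(cohort, label = cohort$event, k = 2,
                                seed = 1, n_folds = 5, n_repeats = 10,
                                num_trees = 200, n_restarts = 50) {
  rfe <- rf_rfe(cohort, label = label, n_folds = n_folds,
                n_repeats = n_repeats, seed = seed,
                num_trees = num_trees)
  strat <- stratify_and_test(cohort, rfe$selected, k = k, seed = seed,
                             n_restarts = n_restarts)
  list(rfe = rfe, stratification = strat)
}

#' Plot Kaplan-Meier curves of a stratification
#'
#' Base-graphics step plot, one line per group, annotated with the
#' log-rank p-value.
#'
#' @param strat A `StratificationResult`.
#' @param main Plot title.
#' @return Invisibly, `strat`.
#' @export
plot_km_curves <- function(strat, main = "Kaplan-Meier survival") {
  cols <- c("#D55E00", "#0072B2")
  xmax <- max(vapply(strat$km_curves, function(cv) max(cv$time),
                     numeric(1)))
  plot(NULL, xlim = c(0, xmax), ylim = c(0, 1),
       xlab = "Time (months)", ylab = "Survival probability",
       main = main)
  for (i in seq_along(strat$km_curves)) {
    cv <- strat$km_curves[[i]]
    graphics::lines(c(0, cv$time), c(1, cv$surv), type = "s",
                    col = cols[(i - 1) %% 2 + 1], lwd = 2)
  }
  lab <- paste0(names(strat$km_curves), " (",
                strat$prognosis_of[seq_along(strat$km_curves)], ")")
  graphics::legend("bottomleft", legend = lab, col = cols, lwd = 2,
                   bty = "n")
  graphics::mtext(sprintf("log-rank p = %.3g", strat$logrank_p),
                  side = 3, line = 0, adj = 1, cex = 0.8)
  invisible(strat)
}
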