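#' Construct an expression study
#'
#' An `ExpressionStudy` bundles a log2-scale gene-by-sample expression
#' matrix with a sample-to-condition map and a gene-to-biotype map. It is
#' the substrate of the differential-expression and network stages.
#'
#' @param values Numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids). Log2 expression units.
#' @param condition Named character vector mapping every sample id to a
#'   condition label. The canonical labels for the three-condition design
#'   are `"ethanol"`, `"E2"` and `"E2_ICI"`, but any labels are accepted.
#' @param biotype Named character vector mapping every gene id to
#'   `"coding"` or `"lncRNA"`.
#' @return An object of class `ExpressionStudy`: a list with elements
#'   `values`, `condition` and `biotype`, validated for duplicate ids,
#'   missing mappings and non-finite values.
#' @export
expression_study <- function(values, condition, biotype) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  genes <- rownames(values)
  samples <- colnames(values)
  if (is.null(genes) || is.null(samples))
    stop("'values' must have gene rownames and sample colnames")
  dup <- genes[duplicated(genes)]
  if (length(dup))
    stop("duplicate gene id(s): ", paste(unique(dup), collapse = ", "))
  dup <- samples[duplicated(samples)]
  if (length(dup))
    stop("duplicate sample id(s): ", paste(unique(dup), collapse = ", "))
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    stop("non-finite value at gene '", genes[bad[1]], "', sample '",
         samples[bad[2]], "'")
  }
  miss <- setdiff(samples, names(condition))
  if (length(miss))
    stop("sample(s) without condition: ", paste(miss, collapse = ", "))
  miss <- setdiff(genes, names(biotype))
  if (length(miss))
    stop("gene(s) without biotype: ", paste(miss, collapse = ", "))
  biotype <- biotype[genes]
  condition <- condition[samples]
  bad <- !biotype %in% c("coding", "lncRNA")
  if (any(bad))
    stop("invalid biotype for gene(s): ",
         paste(genes[bad], collapse = ", "),
         " (must be 'coding' or 'lncRNA')")
  structure(list(values = values,
                 condition = condition,
                 biotype = biotype),
            class = "ExpressionStudy")
}

#' @export
print.ExpressionStudy <- function(x, ...) {
  cat("ExpressionStudy:", nrow(x$values), "genes x", ncol(x$values),
      "samples\n")
  cat("  biotypes:  ", paste(names(table(x$biotype)),
                             table(x$biotype), collapse = ", "), "\n")
  cat("  conditions:", paste(names(table(x$condition)),
                             table(x$condition), collapse = ", "), "\n")
  invisible(x)
}

#' Read an expression study from TSV files
#'
#' @param matrix_path TSV with a header row of sample ids; first column
#'   `gene_id`, remaining columns numeric log2 expression values.
#' @param condition_path Two-column TSV `sample_id<TAB>condition` with a
#'   header; must cover every sample in the matrix.
#' @param annotation_path Two-column TSV `gene_id<TAB>biotype` with a
#'   header; `biotype` in `{coding, lncRNA}`; must cover every gene.
#' @return An [expression_study()] with row/column order as in the file.
#' @export
read_expression_study <- function(matrix_path, condition_path,
                                  annotation_path) {
  raw <- read.delim(matrix_path, header = TRUE, sep = "\t",
                    check.names = FALSE, colClasses = "character")
  if (ncol(raw) < 2) stop("expression matrix needs >= 1 sample column")
  genes <- raw[[1]]
  vals <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop("non-numeric cell at row ", bad[1], " (gene '", genes[bad[1]],
         "'), column ", bad[2], " (sample '", colnames(vals)[bad[2]], "')")
  }
  dimnames(num) <- list(genes, colnames(vals))
  cond <- read.delim(condition_path, header = TRUE, sep = "\t",
                     colClasses = "character")
  annot <- read.delim(annotation_path, header = TRUE, sep = "\t",
                      colClasses = "character")
  expression_study(num,
                   condition = setNames(cond[[2]], cond[[1]]),
                   biotype = setNames(annot[[2]], annot[[1]]))
}

#' Write an expression study to TSV files
#'
#' Inverse of [read_expression_study()]; numeric values are written with
#' 15 significant digits so a write/read round trip reproduces them to
#' better than 1e-12.
#'
#' @param study An `ExpressionStudy`.
#' @param matrix_path,condition_path,annotation_path Output paths.
#' @return Invisibly, the study.
#' @export
write_expression_study <- function(study, matrix_path, condition_path,
                                   annotation_path) {
  stopifnot(inherits(study, "ExpressionStudy"))
  df <- data.frame(gene_id = rownames(study$values),
                   format(study$values, digits = 15, trim = TRUE,
                          scientific = FALSE),
                   check.names = FALSE)
  write.table(df, matrix_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(sample_id = names(study$condition),
                         condition = unname(study$condition)),
              condition_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(gene_id = names(study$biotype),
                         biotype = unname(study$biotype)),
              annotation_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(study)
}

#' Variance-based gene pre-filter
#'
#' Retains the fraction of genes with the largest unbiased sample variance
#' (divisor n-1) across all samples, coding and non-coding genes ranked in
#' one joint pool by default. This mirrors the standard pre-filter applied
#' before co-expression network construction (top 75 percent).
#'
#' @param study An `ExpressionStudy` with at least two samples.
#' @param keep_fraction Fraction of genes to keep, in (0, 1]. The number
#'   kept is `ceiling(keep_fraction * n_genes)`; variance ties are broken
#'   by input order.
#' @param per_biotype If `TRUE`, rank and keep the fraction within each
#'   biotype separately (sensitivity-analysis mode).
#' @return The filtered `ExpressionStudy`; sample set unchanged, gene
#'   order preserved.
#' @export
variance_filter <- function(study, keep_fraction = 0.75,
                            per_biotype = FALSE) {
  stopifnot(inherits(study, "ExpressionStudy"))
  if (!is.numeric(keep_fraction) || length(keep_fraction) != 1 ||
      keep_fraction <= 0 || keep_fraction > 1)
    stop("'keep_fraction' must be in (0, 1]")
  if (ncol(study$values) < 2)
    stop("variance filter needs >= 2 samples")
  v <- apply(study$values, 1, var)
  pick <- function(idx) {
    k <- ceiling(keep_fraction * length(idx))
    ord <- idx[order(-v[idx])]  # stable: ties keep input order
    sort(ord[seq_len(k)])
  }
  keep <- if (per_biotype) {
    sort(unlist(lapply(split(seq_along(v), study$biotype), pick),
                use.names = FALSE))
  } else {
    pick(seq_along(v))
  }
  expression_study(study$values[keep, , drop = FALSE],
                   study$condition, study$biotype[keep])
}

#' Read a gene-set collection from a GMT file
#'
#' Standard GMT dialect: one term per line,
#' `term_id<TAB>description<TAB>gene1<TAB>gene2...`. Terms with no member
#' genes are rejected.
#'
#' @param path GMT file path.
#' @return A `GeneSetCollection`: a named list (names = term ids) whose
#'   elements are lists with `name` (description) and `genes` (character
#'   vector of member ids).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- vector("list", length(lines))
  ids <- character(length(lines))
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3)
      stop("malformed GMT line ", i, ": fewer than 3 fields")
    genes <- parts[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (!length(genes))
      stop("malformed GMT line ", i, ": term '", parts[1],
           "' has no member genes")
    ids[i] <- parts[1]
    sets[[i]] <- list(name = parts[2], genes = genes)
  }
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate term id(s): ", paste(unique(dup), collapse = ", "))
  structure(setNames(sets, ids), class = "GeneSetCollection")
}

#' Write a gene-set collection to GMT
#'
#' @param sets A `GeneSetCollection` as returned by [read_gmt()].
#' @param path Output path.
#' @return Invisibly, `sets`.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(id) {
    paste(c(id, sets[[id]]$name, sets[[id]]$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(sets)
}

#' Construct a survival cohort
#'
#' @param time Nonnegative follow-up time per patient (months).
#' @param event Event indicator per patient, 0 = censored, 1 = event.
#' @param features Numeric patient-by-gene matrix (log2 expression of
#'   candidate genes), rownames = patient ids.
#' @return An object of class `SurvivalCohort` with elements `patients`,
#'   `time`, `event`, `features`.
#' @export
survival_cohort <- function(time, event, features) {
  if (!is.matrix(features) || is.null(rownames(features)))
    stop("'features' must be a matrix with patient rownames")
  patients <- rownames(features)
  if (anyDuplicated(patients))
    stop("duplicate patient id(s): ",
         paste(unique(patients[duplicated(patients)]), collapse = ", "))
  if (length(time) != length(patients) || length(event) != length(patients))
    stop("'time' and 'event' must align with the feature matrix rows")
  if (any(!is.finite(time)) || any(time < 0))
    stop("'time' must be finite and nonnegative")
  if (!all(event %in% c(0, 1)))
    stop("'event' must be 0/1")
  structure(list(patients = patients,
                 time = as.numeric(time),
                 event = as.integer(event),
                 features = features),
            class = "SurvivalCohort")
}

#' Read a survival cohort from TSV
#'
#' Expected columns: `patient_id`, `time`, `event`, then one column per
#' candidate gene.
#'
#' @param path TSV file path.
#' @return A [survival_cohort()].
#' @export
read_cohort <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
  need <- c("patient_id", "time", "event")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("cohort file missing column(s): ", paste(miss, collapse = ", "))
  feats <- as.matrix(df[, setdiff(colnames(df), need), drop = FALSE])
  rownames(feats) <- df$patient_id
  survival_cohort(df$time, df$event, feats)
}

#' Write a survival cohort to TSV
#'
#' @param cohort A `SurvivalCohort`.
#' @param path Output path.
#' @return Invisibly, the cohort.
#' @export
write_cohort <- function(cohort, path) {
  df <- data.frame(patient_id = cohort$patients,
                   time = format(cohort$time, digits = 15, trim = TRUE,
                                 scientific = FALSE),
                   event = cohort$event,
                   format(cohort$features, digits = 15, trim = TRUE,
                          scientific = FALSE),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(cohort)
}
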