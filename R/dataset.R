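#' Construct a two-condition spot-level expression dataset
#'
#' The central container of the package: normalized linear-scale intensities
#' for every retained microarray spot, in two conditions with biological
#' replicates, plus the spot-to-gene annotation. A gene may be probed
#' redundantly by several spots; all downstream statistics (AVE, REV, COR)
#' account for that redundancy.
#'
#' @param spot_id character vector of unique spot identifiers.
#' @param gene character vector, same length as `spot_id`: the gene symbol
#'   probed by each spot. Symbols are case-sensitive and matched exactly.
#' @param values named list of numeric matrices, one per condition, each with
#'   `length(spot_id)` rows (spots, in the same order) and one column per
#'   biological replicate. All values must be finite and strictly positive;
#'   rows violating this should be dropped with [drop_bad_spots()] before
#'   construction.
#' @param conditions character(2): labels of the reference and experimental
#'   condition, in that order (defaults `c("N", "L")`).
#'
#' @return An object of class `fabric_dataset`: a list with elements
#'   `spot_id`, `gene`, `values`, `conditions`, `n_replicates` (named integer
#'   vector), and `n_dropped` (spots removed by filtering, 0 at construction).
#' @examples
#' ds <- fabric_dataset(
#'   spot_id = c("s1", "s2"), gene = c("A", "B"),
#'   values = list(N = matrix(1:8, 2), L = matrix(2:9, 2))
#' )
#' ds
#' @export
fabric_dataset <- function(spot_id, gene, values,
                           conditions = names(values)) {
  spot_id <- as.character(spot_id)
  gene <- as.character(gene)
  if (length(spot_id) != length(gene)) {
    stop("`spot_id` and `gene` must have the same length")
  }
  if (anyDuplicated(spot_id)) stop("spot identifiers must be unique")
  if (!is.list(values) || length(values) < 2) {
    stop("`values` must be a list of one matrix per condition (>= 2)")
  }
  if (is.null(conditions)) stop("conditions must be named")
  values <- lapply(values, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    dimnames(m) <- list(spot_id, NULL)
    m
  })
  names(values) <- conditions
  for (cond in conditions) {
    m <- values[[cond]]
    if (nrow(m) != length(spot_id)) {
      stop("value matrix for condition '", cond, "' has wrong row count")
    }
    if (ncol(m) < 2) {
      stop("condition '", cond, "' needs >= 2 replicates")
    }
    if (any(!is.finite(m)) || any(m <= 0)) {
      stop("all retained values must be finite and > 0; ",
           "use drop_bad_spots() first")
    }
  }
  structure(
    list(
      spot_id = spot_id,
      gene = gene,
      values = values,
      conditions = conditions,
      n_replicates = vapply(values, ncol, integer(1)),
      n_dropped = 0L
    ),
    class = "fabric_dataset"
  )
}

#' @export
print.fabric_dataset <- function(x, ...) {
  cat("fabric_dataset:", length(x$spot_id), "spots /",
      length(unique(x$gene)), "genes\n")
  cat("conditions:",
      paste(sprintf("%s (%d replicates)", x$conditions, x$n_replicates),
            collapse = ", "), "\n")
  if (x$n_dropped > 0) cat("spots dropped by filtering:", x$n_dropped, "\n")
  invisible(x)
}

#' Genes quantified in a dataset
#'
#' @param dataset a [fabric_dataset()].
#' @return character vector of unique gene symbols, in first-appearance order.
#' @export
quantified_genes <- function(dataset) {
  unique(dataset$gene)
}

#' Spot-level value matrix of one gene in one condition
#'
#' Rows are the gene's spots in file order, columns are replicates.
#'
#' @param dataset a [fabric_dataset()].
#' @param gene gene symbol.
#' @param condition condition label.
#' @return numeric matrix (spots x replicates).
#' @export
gene_spot_matrix <- function(dataset, gene, condition) {
  idx <- which(dataset$gene == gene)
  if (length(idx) == 0) stop("unknown gene: ", gene)
  if (!condition %in% dataset$conditions) {
    stop("unknown condition: ", condition)
  }
  dataset$values[[condition]][idx, , drop = FALSE]
}

#' Per-replicate gene values (spot-averaged)
#'
#' Averages a gene's redundant spots within each biological replicate, giving
#' one value per replicate: the sampling unit for the between-condition
#' heteroscedastic t-test.
#'
#' @inheritParams gene_spot_matrix
#' @return numeric vector of length `n_replicates[condition]`.
#' @export
gene_replicate_values <- function(dataset, gene, condition) {
  colMeans(gene_spot_matrix(dataset, gene, condition))
}

#' Drop spots with missing or non-positive intensities
#'
#' Mirrors the upstream quality filter of the experimental protocol: a spot
#' carrying any missing, non-finite, or non-positive value in either
#' condition is removed entirely (from both conditions). Other spots of the
#' same gene are kept. Idempotent.
#'
#' @param spot_id,gene,values as in [fabric_dataset()], except `values` may
#'   contain `NA`/non-positive entries.
#' @param conditions condition labels (default the names of `values`).
#' @return list with elements `dataset` (a clean [fabric_dataset()]) and
#'   `n_dropped` (number of removed spots). Errors if no spot survives.
#' @export
drop_bad_spots <- function(spot_id, gene, values,
                           conditions = names(values)) {
  bad <- Reduce(`|`, lapply(values, function(m) {
    m <- as.matrix(m)
    apply(m, 1, function(r) any(!is.finite(r)) || any(r <= 0))
  }))
  keep <- !bad
  if (!any(keep)) stop("no usable spots after filtering (empty dataset)")
  ds <- fabric_dataset(
    spot_id = spot_id[keep],
    gene = gene[keep],
    values = lapply(values, function(m) as.matrix(m)[keep, , drop = FALSE]),
    conditions = conditions
  )
  ds$n_dropped <- sum(bad)
  list(dataset = ds, n_dropped = sum(bad))
}

#' Analysis configuration
#'
#' Bundles the tunable statistical parameters of the fabric analysis.
#'
#' @param alpha two-sided significance level for correlation cut-offs and the
#'   regulation t-test (default 0.05).
#' @param independence_threshold absolute correlation below which a gene pair
#'   is called independently expressed (default 0.05). Must stay below the
#'   significance cut-off for any spot count.
#' @param cv_correction logical: apply the chi-square mid-interval correction
#'   to the coefficient of variation when computing REV (default `TRUE`).
#' @param gch_exponent exponent applied to the mean squared correlation in
#'   the gene commanding height (default 4).
#' @param seed integer seed for any randomized routine.
#' @return object of class `fabric_config` (a validated list).
#' @export
fabric_config <- function(alpha = 0.05, independence_threshold = 0.05,
                          cv_correction = TRUE, gch_exponent = 4,
                          seed = 1L) {
  stopifnot(alpha > 0, alpha < 1, independence_threshold > 0,
            is.logical(cv_correction), gch_exponent > 0)
  structure(
    list(alpha = alpha,
         independence_threshold = independence_threshold,
         cv_correction = isTRUE(cv_correction),
         gch_exponent = gch_exponent,
         seed = as.integer(seed)),
    class = "fabric_config"
  )
}
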