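#' Average expression level (AVE) of a gene
#'
#' The mean normalized intensity over all biological replicates of all spots
#' redundantly probing the gene in one condition.
#'
#' @param dataset a [fabric_dataset()].
#' @param gene gene symbol.
#' @param condition condition label.
#' @return numeric scalar, AVE (unitless, on the normalized intensity scale).
#' @export
compute_ave <- function(dataset, gene, condition) {
  mean(gene_spot_matrix(dataset, gene, condition))
}

#' Chi-square mid-interval correction factor for a coefficient of variation
#'
#' The sample CV from n replicates is a biased, noisy estimate of the true
#' CV. The mid-interval correction multiplies it by the average of the two
#' chi-square confidence bounds of the standard deviation,
#' c = (sqrt(nu/chisq(1-alpha/2, nu)) + sqrt(nu/chisq(alpha/2, nu))) / 2,
#' with nu the pooled degrees of freedom. At nu = 3 (single spot, four
#' replicates) c = 2.1475.
#'
#' @param nu pooled degrees of freedom (s spots x (n - 1)).
#' @param level confidence level of the interval (default 0.95).
#' @return correction factor c >= 1.
#' @export
rev_correction_factor <- function(nu, level = 0.95) {
  stopifnot(nu >= 1)
  a <- (1 - level) / 2
  0.5 * (sqrt(nu / stats::qchisq(1 - a, nu)) +
         sqrt(nu / stats::qchisq(a, nu)))
}

#' Relative expression variation (REV) of a gene
#'
#' REV is the corrected coefficient of variation, in percent, of a gene's
#' expression across biological replicates:
#' `100 * c * pooled_sd / AVE`. The pooled standard deviation combines the
#' within-spot replicate variances of the gene's s redundant spots with
#' nu = s*(n-1) degrees of freedom, so constant intensity offsets between
#' spots do not inflate REV. A low REV indicates tight homeostatic control
#' of the transcript's abundance.
#'
#' @inheritParams compute_ave
#' @param cv_correction apply the chi-square mid-interval correction
#'   ([rev_correction_factor()]); default `TRUE`.
#' @return numeric scalar, REV in percent (>= 0).
#' @export
compute_rev <- function(dataset, gene, condition, cv_correction = TRUE) {
  m <- gene_spot_matrix(dataset, gene, condition)
  n <- ncol(m)
  if (n < 2) stop("REV needs >= 2 replicates")
  ave <- mean(m)
  vars <- apply(m, 1, stats::var)
  pooled_sd <- sqrt(mean(vars))          # equal replicate count per spot
  nu <- nrow(m) * (n - 1)
  cc <- if (isTRUE(cv_correction)) rev_correction_factor(nu) else 1
  100 * cc * pooled_sd / ave
}

#' Critical correlation for significance at a given spot count
#'
#' Two genes probed by s_i and s_j spots over n replicates contribute
#' n_points = n * min(s_i, s_j) paired values to their Pearson correlation.
#' The two-tailed critical |r| at level alpha is the t-distribution closed
#' form r_c = t_c / sqrt(t_c^2 + df), df = n_points - 2. With n = 4 this
#' gives 0.950 for single-spot pairs, 0.71 for two spots, and 0.58 for
#' three: redundant probing buys sensitivity.
#'
#' @param s_i,s_j spot counts of the two genes (>= 1).
#' @param n replicates per condition (>= 2).
#' @param alpha two-sided significance level (default 0.05).
#' @return critical absolute Pearson correlation in (0, 1).
#' @export
correlation_cutoff <- function(s_i, s_j, n, alpha = 0.05) {
  stopifnot(s_i >= 1, s_j >= 1, n >= 2)
  n_points <- n * min(s_i, s_j)
  df <- n_points - 2
  if (df <= 0) stop("insufficient data: need n * min(s_i, s_j) > 2")
  t_c <- stats::qt(1 - alpha / 2, df)
  t_c / sqrt(t_c^2 + df)
}

#' Expression correlation (COR) of a gene pair
#'
#' Pearson correlation across n * s_min paired values, where spot k of gene
#' i is paired with spot k of gene j (k = 1..min(s_i, s_j), spots in file
#' order) within each replicate. If either vector has zero variance the
#' correlation is undefined and reported as `NA` with class "unclassified".
#'
#' @param dataset a [fabric_dataset()].
#' @param gene_i,gene_j gene symbols.
#' @param condition condition label.
#' @return list with elements `cor` (numeric or `NA`) and `n_points`.
#' @export
compute_cor <- function(dataset, gene_i, gene_j, condition) {
  mi <- gene_spot_matrix(dataset, gene_i, condition)
  mj <- gene_spot_matrix(dataset, gene_j, condition)
  s_min <- min(nrow(mi), nrow(mj))
  vi <- as.vector(mi[seq_len(s_min), , drop = FALSE])
  vj <- as.vector(mj[seq_len(s_min), , drop = FALSE])
  n_points <- length(vi)
  if (stats::sd(vi) == 0 || stats::sd(vj) == 0) {
    return(list(cor = NA_real_, n_points = n_points))
  }
  list(cor = stats::cor(vi, vj), n_points = n_points)
}

#' Classify a gene pair's expression relationship
#'
#' Synergistic if the correlation reaches the positive significance cut-off
#' (in-phase oscillation across replicates), antagonistic if it reaches the
#' negative cut-off, independent if |COR| falls below the independence
#' threshold, and unclassified otherwise (including undefined correlations).
#' The classes are exhaustive and mutually exclusive.
#'
#' @param cor Pearson correlation in `[-1, 1]`, or `NA`.
#' @param n_points number of paired values used.
#' @param alpha two-sided significance level (default 0.05).
#' @param independence_threshold absolute-correlation bound for independence
#'   (default 0.05).
#' @return one of `"synergistic"`, `"antagonistic"`, `"independent"`,
#'   `"unclassified"`.
#' @export
classify_pair <- function(cor, n_points, alpha = 0.05,
                          independence_threshold = 0.05) {
  if (is.na(cor)) return("unclassified")
  stopifnot(cor >= -1, cor <= 1)
  df <- n_points - 2
  t_c <- stats::qt(1 - alpha / 2, df)
  r_c <- t_c / sqrt(t_c^2 + df)
  if (cor >= r_c) "synergistic"
  else if (cor <= -r_c) "antagonistic"
  else if (abs(cor) < independence_threshold) "independent"
  else "unclassified"
}

#' Per-gene primary statistics for all genes
#'
#' Computes AVE, REV, and the spot count of every quantified gene in each
#' requested condition.
#'
#' @param dataset a [fabric_dataset()].
#' @param config a [fabric_config()].
#' @param conditions conditions to process (default: all in the dataset).
#' @return data.frame with columns `gene`, `condition`, `ave`, `rev`,
#'   `n_spots`, `n_replicates`.
#' @export
gene_stats <- function(dataset, config = fabric_config(),
                       conditions = dataset$conditions) {
  genes <- quantified_genes(dataset)
  spot_counts <- table(dataset$gene)[genes]
  out <- do.call(rbind, lapply(conditions, function(cond) {
    ave <- vapply(genes, compute_ave, numeric(1),
                  dataset = dataset, condition = cond)
    rev <- vapply(genes, compute_rev, numeric(1),
                  dataset = dataset, condition = cond,
                  cv_correction = config$cv_correction)
    data.frame(gene = genes, condition = cond, ave = ave, rev = rev,
               n_spots = as.integer(spot_counts),
               n_replicates = dataset$n_replicates[[cond]],
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  rownames(out) <- NULL
  out
}

#' Pairwise correlations and classifications
#'
#' Computes COR and its class for every distinct pair within `genes_a`
#' (when `genes_b` is `NULL`), or for every cross pair between `genes_a`
#' and `genes_b` (shared genes contribute no self-pair, and each distinct
#' pair appears once).
#'
#' @param dataset a [fabric_dataset()].
#' @param genes_a character vector of gene symbols (subset of quantified
#'   genes; absent symbols are dropped with a warning).
#' @param genes_b optional second gene list for cross-set pairs.
#' @param condition condition label.
#' @param config a [fabric_config()].
#' @return data.frame with columns `gene_i`, `gene_j`, `condition`, `cor`,
#'   `n_points`, `cls`.
#' @export
pair_stats <- function(dataset, genes_a, genes_b = NULL,
                       condition = dataset$conditions[[1]],
                       config = fabric_config()) {
  present <- quantified_genes(dataset)
  keep_known <- function(g) {
    absent <- setdiff(g, present)
    if (length(absent) > 0) {
      warning("dropping ", length(absent),
              " gene(s) absent from the dataset: ",
              paste(utils::head(absent, 5), collapse = ", "),
              if (length(absent) > 5) ", ..." else "")
    }
    intersect(g, present)
  }
  genes_a <- keep_known(unique(genes_a))
  pairs <- if (is.null(genes_b)) {
    if (length(genes_a) < 2) stop("need >= 2 quantified genes for pairs")
    idx <- utils::combn(length(genes_a), 2)
    data.frame(gene_i = genes_a[idx[1, ]], gene_j = genes_a[idx[2, ]],
               stringsAsFactors = FALSE)
  } else {
    genes_b <- keep_known(unique(genes_b))
    grid <- expand.grid(gene_i = genes_a, gene_j = genes_b,
                        stringsAsFactors = FALSE)
    grid <- grid[grid$gene_i != grid$gene_j, , drop = FALSE]
    # one record per distinct unordered pair
    key <- ifelse(grid$gene_i < grid$gene_j,
                  paste(grid$gene_i, grid$gene_j),
                  paste(grid$gene_j, grid$gene_i))
    grid[!duplicated(key), , drop = FALSE]
  }
  res <- mapply(function(gi, gj) {
    cc <- compute_cor(dataset, gi, gj, condition)
    cls <- classify_pair(cc$cor, cc$n_points, config$alpha,
                         config$independence_threshold)
    list(cor = cc$cor, n_points = cc$n_points, cls = cls)
  }, pairs$gene_i, pairs$gene_j, SIMPLIFY = FALSE)
  data.frame(
    gene_i = pairs$gene_i,
    gene_j = pairs$gene_j,
    condition = condition,
    cor = vapply(res, `[[`, numeric(1), "cor"),
    n_points = vapply(res, function(r) as.integer(r$n_points), integer(1)),
    cls = vapply(res, `[[`, character(1), "cls"),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Number of distinct gene pairs among N genes
#'
#' The pair bookkeeping of a full-transcriptome correlation analysis:
#' N*(N-1)/2 distinct correlations (192,168,210 for 19,605 genes).
#'
#' @param n_genes number of quantified genes.
#' @return count of distinct unordered pairs.
#' @export
count_distinct_pairs <- function(n_genes) {
  n_genes * (n_genes - 1) / 2
}
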