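#' Relative expression control (REC)
#'
#' The transcriptome-median REV divided by the gene's own REV, in the same
#' condition. Genes under tight homeostatic control (small REV) score high;
#' the median gene scores exactly 1.
#'
#' @param rev_gene the gene's REV (%).
#' @param rev_median median REV over all quantified genes in the condition.
#' @param cap value reported when `rev_gene` is 0 (infinite control);
#'   accompanied by a warning.
#' @return numeric scalar, REC > 0.
#' @export
compute_rec <- function(rev_gene, rev_median, cap = 1e6) {
  stopifnot(rev_median > 0, rev_gene >= 0)
  if (rev_gene == 0) {
    warning("REV = 0: infinite expression control, capping REC at ", cap)
    return(cap)
  }
  rev_median / rev_gene
}

#' Coordination degree from partner counts
#'
#' COORD = 100 * (n_syn + n_ant - n_ind) / n_partners: significant
#' synergisms and antagonisms both witness coordination, independence
#' witnesses its absence, and unclassified partners count only in the
#' denominator. Applies unchanged to a single gene against the rest of the
#' transcriptome (n_partners = N - 1), to a pathway's internal pair universe,
#' or to a pathway pair.
#'
#' @param n_syn,n_ant,n_ind counts of significantly synergistic,
#'   antagonistic, and independent partners (or pairs).
#' @param n_partners size of the partner (or pair) universe.
#' @return coordination degree in percent, within `[-100, 100]`.
#' @export
coordination_degree <- function(n_syn, n_ant, n_ind, n_partners) {
  stopifnot(n_partners > 0, n_syn + n_ant + n_ind <= n_partners)
  100 * (n_syn + n_ant - n_ind) / n_partners
}

#' Coordination degree of one gene from pair classifications
#'
#' @param gene gene symbol.
#' @param pairs pair table from [pair_stats()] (one condition); every
#'   partner of `gene` in the table enters the denominator.
#' @return list with `coord` (%), `n_syn`, `n_ant`, `n_ind`, `n_partners`.
#' @export
compute_coord_gene <- function(gene, pairs) {
  sel <- pairs$gene_i == gene | pairs$gene_j == gene
  if (!any(sel)) stop("gene '", gene, "' has no partners in the pair table")
  cls <- pairs$cls[sel]
  n_syn <- sum(cls == "synergistic")
  n_ant <- sum(cls == "antagonistic")
  n_ind <- sum(cls == "independent")
  n_partners <- length(cls)
  list(coord = coordination_degree(n_syn, n_ant, n_ind, n_partners),
       n_syn = n_syn, n_ant = n_ant, n_ind = n_ind,
       n_partners = n_partners)
}

#' Gene commanding height (GCH)
#'
#' Combines expression control and coordination power into a single score
#' used to rank genes: gch = rec * exp(exponent * mean(COR^2)), the mean
#' squared correlation taken over all the gene's partners. The top-ranked
#' gene is the Gene Master Regulator of the profiled phenotype.
#'
#' @param rec relative expression control (> 0).
#' @param mean_squared_cor average of squared correlations with all
#'   partners, in `[0, 1]`.
#' @param exponent amplification exponent (default 4).
#' @return numeric scalar > 0.
#' @export
compute_gch <- function(rec, mean_squared_cor, exponent = 4) {
  stopifnot(rec > 0, mean_squared_cor >= 0, mean_squared_cor <= 1)
  rec * exp(exponent * mean_squared_cor)
}

#' Derived per-gene statistics (REC, COORD, GCH)
#'
#' Combines the primary statistics and a pair table into the derived
#' characteristics of every gene that appears in the pair table. The
#' transcriptome-median REV is taken over all genes of `stats` in the same
#' condition, so `stats` should cover the full quantified transcriptome
#' even when pairs were computed for a subset.
#'
#' @param stats output of [gene_stats()].
#' @param pairs output of [pair_stats()] (a single condition).
#' @param config a [fabric_config()].
#' @return data.frame with columns `gene`, `condition`, `rec`, `coord`,
#'   `gch`, `n_syn`, `n_ant`, `n_ind`, `n_partners`.
#' @export
derived_stats <- function(stats, pairs, config = fabric_config()) {
  cond <- unique(pairs$condition)
  if (length(cond) != 1) stop("`pairs` must hold a single condition")
  st <- stats[stats$condition == cond, ]
  rev_median <- stats::median(st$rev)
  genes <- unique(c(pairs$gene_i, pairs$gene_j))
  rows <- lapply(genes, function(g) {
    cg <- compute_coord_gene(g, pairs)
    sel <- pairs$gene_i == g | pairs$gene_j == g
    msq <- mean(pairs$cor[sel]^2, na.rm = TRUE)
    if (is.nan(msq)) msq <- 0
    rec <- compute_rec(st$rev[st$gene == g], rev_median)
    data.frame(gene = g, condition = cond, rec = rec, coord = cg$coord,
               gch = compute_gch(rec, msq, config$gch_exponent),
               n_syn = cg$n_syn, n_ant = cg$n_ant, n_ind = cg$n_ind,
               n_partners = cg$n_partners,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Gene-set average of a per-gene statistic
#'
#' Arithmetic mean over the quantified members of the set only, with the
#' coverage (quantified out of assigned) reported alongside.
#'
#' @param stats data.frame with a `gene` column and the target field, for a
#'   single condition.
#' @param set a [gene_set()].
#' @param field name of the column to average.
#' @return list with `mean`, `n_quantified`, `n_assigned`, `coverage`
#'   (e.g. `"130/156"`).
#' @export
pathway_average <- function(stats, set, field) {
  members <- stats[stats$gene %in% set$genes, , drop = FALSE]
  if (nrow(members) == 0) {
    stop("no quantified members in gene set '", set$name, "'")
  }
  list(mean = mean(members[[field]]),
       n_quantified = nrow(members),
       n_assigned = length(set$genes),
       coverage = paste0(nrow(members), "/", length(set$genes)))
}
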