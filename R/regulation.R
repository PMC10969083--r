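#' Signed expression ratio between conditions
#'
#' x = AVE_L / AVE_N when expression rose, and -AVE_N / AVE_L when it fell:
#' the magnitude is always the fold-change (>= 1) and the sign encodes the
#' direction (negative for down-regulation).
#'
#' @param ave_n,ave_l average expression levels in the reference and
#'   experimental condition (> 0).
#' @return signed ratio with `|x| >= 1`.
#' @export
expression_ratio <- function(ave_n, ave_l) {
  stopifnot(ave_n > 0, ave_l > 0)
  if (ave_l >= ave_n) ave_l / ave_n else -ave_n / ave_l
}

#' Heteroscedastic (Welch) t-test p-value for a gene
#'
#' Two-tailed unequal-variance t-test of equal means with
#' Welch-Satterthwaite degrees of freedom, applied to the per-replicate
#' spot-averaged gene values (the biological replicate is the sampling
#' unit). Degenerate case of zero variance in both groups with equal means
#' returns p = 1.
#'
#' @param values_n,values_l numeric vectors of per-replicate gene values
#'   (>= 2 each).
#' @return two-tailed p-value.
#' @export
welch_p <- function(values_n, values_l) {
  stopifnot(length(values_n) >= 2, length(values_l) >= 2)
  if (stats::sd(values_n) == 0 && stats::sd(values_l) == 0) {
    return(if (mean(values_n) == mean(values_l)) 1 else 0)
  }
  stats::t.test(values_n, values_l, var.equal = FALSE)$p.value
}

#' Per-gene absolute fold-change cut-off (CUT)
#'
#' A uniform fold-change cut-off (1.5x, 2x) is too stringent for stably
#' expressed genes and too lax for noisy ones. CUT adapts the threshold to
#' the gene's own expression variability in the two conditions:
#' CUT = 1 + sqrt(2) * sqrt(REV_N^2 + REV_L^2) / 100.
#'
#' @param rev_n,rev_l the gene's REVs (%) in the two conditions (>= 0).
#' @return absolute fold-change threshold > 1 (equal to 1 only when both
#'   REVs are 0).
#' @export
compute_cut <- function(rev_n, rev_l) {
  stopifnot(rev_n >= 0, rev_l >= 0)
  1 + sqrt(2) * sqrt(rev_n^2 + rev_l^2) / 100
}

#' Composite significant-regulation call
#'
#' A gene is significantly up-regulated when x >= CUT and p < alpha, down
#' when x <= -CUT and p < alpha, and unregulated otherwise. Because CUT is
#' gene-specific, the call can disagree with the fixed 1.5x convention in
#' both directions.
#'
#' @param x signed expression ratio ([expression_ratio()]).
#' @param p Welch p-value.
#' @param cut the gene's CUT ([compute_cut()]).
#' @param alpha significance level (default 0.05).
#' @return one of `"up"`, `"down"`, `"none"`.
#' @export
regulation_call <- function(x, p, cut, alpha = 0.05) {
  if (p < alpha && x >= cut) "up"
  else if (p < alpha && x <= -cut) "down"
  else "none"
}

#' Weighted individual regulation (WIR)
#'
#' Signed contribution of a gene to the overall transcriptomic change,
#' applied to every gene regardless of its regulation call:
#' wir = AVE_N * (|x| - 1) * sign(x) * (1 - p). Abundant genes with large,
#' confident fold-changes dominate; an unchanged gene (x = 1) contributes 0.
#'
#' @param ave_n reference-condition average expression level.
#' @param x signed expression ratio.
#' @param p Welch p-value (uncapped).
#' @return signed WIR in AVE units.
#' @export
compute_wir <- function(ave_n, x, p) {
  ave_n * (abs(x) - 1) * sign(x) * (1 - p)
}

#' Change in coordination degree between conditions
#'
#' Simple difference in percentage points, COORD_L - COORD_N; negative
#' values indicate decoupling of the gene from the rest of the fabric.
#'
#' @param coord_n,coord_l coordination degrees (%) in the two conditions.
#' @return difference in percentage points.
#' @export
compute_delta_coord <- function(coord_n, coord_l) {
  coord_l - coord_n
}

#' Change in expression control between conditions
#'
#' Reported in percent: (REC_L - REC_N) * 100. Positive values mean the
#' transcript's abundance came under tighter homeostatic control in the
#' experimental condition.
#'
#' @param rec_n,rec_l relative expression control in the two conditions.
#' @return change in percent.
#' @export
compute_delta_rec <- function(rec_n, rec_l) {
  (rec_l - rec_n) * 100
}

#' Regulation table for all genes
#'
#' Per-gene between-condition comparison: AVEs, signed expression ratio,
#' Welch p, gene-specific CUT, regulation call, and WIR. When derived
#' statistics for both conditions are supplied, delta-REC and delta-COORD
#' columns are merged in.
#'
#' @param dataset a [fabric_dataset()].
#' @param config a [fabric_config()].
#' @param stats optional precomputed [gene_stats()] (both conditions);
#'   computed on the fly when `NULL`.
#' @param derived optional [derived_stats()] output covering both
#'   conditions (row-bound), used for `delta_rec`/`delta_coord`.
#' @param ref,exp reference and experimental condition labels (defaults:
#'   first and second dataset condition).
#' @return data.frame with columns `gene`, `ave_n`, `ave_l`, `x`, `p`,
#'   `cut`, `call`, `wir`, and (when available) `delta_rec`, `delta_coord`.
#' @export
regulation_table <- function(dataset, config = fabric_config(),
                             stats = NULL, derived = NULL,
                             ref = dataset$conditions[[1]],
                             exp = dataset$conditions[[2]]) {
  if (is.null(stats)) stats <- gene_stats(dataset, config)
  genes <- quantified_genes(dataset)
  sn <- stats[stats$condition == ref, ]
  sl <- stats[stats$condition == exp, ]
  rows <- lapply(genes, function(g) {
    ave_n <- sn$ave[sn$gene == g]
    ave_l <- sl$ave[sl$gene == g]
    x <- expression_ratio(ave_n, ave_l)
    p <- welch_p(gene_replicate_values(dataset, g, ref),
                 gene_replicate_values(dataset, g, exp))
    cut <- compute_cut(sn$rev[sn$gene == g], sl$rev[sl$gene == g])
    data.frame(gene = g, ave_n = ave_n, ave_l = ave_l, x = x, p = p,
               cut = cut, call = regulation_call(x, p, cut, config$alpha),
               wir = compute_wir(ave_n, x, p),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(derived)) {
    dn <- derived[derived$condition == ref, ]
    dl <- derived[derived$condition == exp, ]
    both <- intersect(dn$gene, dl$gene)
    idx <- match(out$gene, both)
    out$delta_rec <- compute_delta_rec(
      dn$rec[match(out$gene, dn$gene)],
      dl$rec[match(out$gene, dl$gene)])
    out$delta_coord <- compute_delta_coord(
      dn$coord[match(out$gene, dn$gene)],
      dl$coord[match(out$gene, dl$gene)])
    out$delta_rec[is.na(idx)] <- NA_real_
    out$delta_coord[is.na(idx)] <- NA_real_
  }
  out
}

#' Compare CUT-based calls with the fixed 1.5x convention
#'
#' Partitions the genes into the four disagreement categories between the
#' per-gene CUT criterion and the traditional uniform fold-change rule
#' (both requiring p < alpha): falsely up/down (pass 1.5x but not CUT) and
#' missed up/down (pass CUT but not 1.5x).
#'
#' @param regulation output of [regulation_table()].
#' @param fixed_cut the uniform threshold (default 1.5).
#' @param alpha significance level (default 0.05).
#' @return data.frame `regulation` with an added `category` column taking
#'   values `"falsely_up"`, `"falsely_down"`, `"missed_up"`,
#'   `"missed_down"`, or `"concordant"`.
#' @export
compare_fixed_cutoff <- function(regulation, fixed_cut = 1.5,
                                 alpha = 0.05) {
  sig <- regulation$p < alpha
  x <- regulation$x
  cut <- regulation$cut
  fixed_call <- ifelse(sig & x >= fixed_cut, "up",
                ifelse(sig & x <= -fixed_cut, "down", "none"))
  category <- rep("concordant", nrow(regulation))
  category[fixed_call == "up" & regulation$call != "up"] <- "falsely_up"
  category[fixed_call == "down" & regulation$call != "down"] <- "falsely_down"
  category[fixed_call != "up" & regulation$call == "up"] <- "missed_up"
  category[fixed_call != "down" & regulation$call == "down"] <- "missed_down"
  regulation$category <- category
  regulation
}
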