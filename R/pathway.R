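#' Weighted pathway regulation (WPR)
#'
#' Root-mean-square of the member genes' WIRs: sign-blind, dominated by the
#' pathway's largest individual contributions.
#'
#' @param wirs numeric vector of WIRs of the set's quantified members.
#' @return WPR >= 0; 0 iff every member WIR is 0.
#' @export
compute_wpr <- function(wirs) {
  if (length(wirs) == 0) stop("empty gene set: no WIRs to aggregate")
  sqrt(mean(wirs^2))
}

#' Intra-pathway coordination degree
#'
#' Counts the significant pair classes over the G*(G-1)/2 distinct pairs of
#' a set's quantified members and reports
#' COORD = 100 * (S + A - I) / (G*(G-1)): the denominator is the ordered
#' pair count, so the reported percentages are half of the naive
#' distinct-pair fractions. A 55-gene set with (302, 246, 54) significant
#' pairs gives 16.63%.
#'
#' @param pairs pair table from [pair_stats()] (one condition).
#' @param set a [gene_set()].
#' @param condition condition label recorded in the output.
#' @return data.frame (one row) with columns `set_a`, `set_b`, `condition`,
#'   `n_syn`, `n_ant`, `n_ind`, `n_pairs`, `coord`.
#' @export
intra_pathway_coord <- function(pairs, set,
                                condition = unique(pairs$condition)) {
  members <- unique(c(pairs$gene_i, pairs$gene_j))
  members <- intersect(members, set$genes)
  g <- length(members)
  if (g < 2) stop("gene set '", set$name, "' has < 2 quantified members")
  sel <- pairs$gene_i %in% members & pairs$gene_j %in% members
  cls <- pairs$cls[sel]
  counts <- c(n_syn = sum(cls == "synergistic"),
              n_ant = sum(cls == "antagonistic"),
              n_ind = sum(cls == "independent"))
  n_pairs <- g * (g - 1)
  data.frame(set_a = set$name, set_b = set$name, condition = condition,
             n_syn = counts[["n_syn"]], n_ant = counts[["n_ant"]],
             n_ind = counts[["n_ind"]], n_pairs = n_pairs,
             coord = coordination_degree(counts[["n_syn"]],
                                         counts[["n_ant"]],
                                         counts[["n_ind"]], n_pairs),
             stringsAsFactors = FALSE)
}

#' Inter-pathway coordination degree
#'
#' Coupling of two gene sets: all (a, b) pairs with a in A, b in B, a != b,
#' each distinct pair counted once; genes shared by both sets contribute no
#' self-pair. The denominator is |A|*|B| - |A intersect B|, and
#' COORD = 100 * (S + A - I) / n_pairs.
#'
#' @param pairs pair table from [pair_stats()] covering the cross pairs
#'   (one condition).
#' @param set_a,set_b [gene_set()] objects.
#' @param condition condition label recorded in the output.
#' @return data.frame as in [intra_pathway_coord()].
#' @export
inter_pathway_coord <- function(pairs, set_a, set_b,
                                condition = unique(pairs$condition)) {
  quantified <- unique(c(pairs$gene_i, pairs$gene_j))
  a <- intersect(set_a$genes, quantified)
  b <- intersect(set_b$genes, quantified)
  if (length(a) == 0 || length(b) == 0) {
    stop("a gene set has no quantified members")
  }
  cross <- (pairs$gene_i %in% a & pairs$gene_j %in% b) |
           (pairs$gene_i %in% b & pairs$gene_j %in% a)
  cls <- pairs$cls[cross]
  n_pairs <- length(a) * length(b) - length(intersect(a, b))
  counts <- c(n_syn = sum(cls == "synergistic"),
              n_ant = sum(cls == "antagonistic"),
              n_ind = sum(cls == "independent"))
  data.frame(set_a = set_a$name, set_b = set_b$name, condition = condition,
             n_syn = counts[["n_syn"]], n_ant = counts[["n_ant"]],
             n_ind = counts[["n_ind"]], n_pairs = n_pairs,
             coord = coordination_degree(counts[["n_syn"]],
                                         counts[["n_ant"]],
                                         counts[["n_ind"]], n_pairs),
             stringsAsFactors = FALSE)
}

#' Signed remodeling ratio of a coordination degree
#'
#' Fold-change of a coupling between conditions, with magnitude >= 1 and a
#' negative sign when the coupling weakened: 13.82% dropping to 2.91% is
#' reported as -4.75x.
#'
#' @param coord_n,coord_l coordination degrees (%) in the reference and
#'   experimental condition (both nonzero).
#' @return signed fold; `NA` with a warning when `coord_l` is 0.
#' @export
remodeling_ratio <- function(coord_n, coord_l) {
  if (coord_l == 0 || coord_n == 0) {
    warning("remodeling ratio undefined for a zero coordination degree")
    return(NA_real_)
  }
  if (abs(coord_l) >= abs(coord_n)) abs(coord_l / coord_n)
  else -abs(coord_n / coord_l)
}

#' Pathway-level regulation and control summary
#'
#' One row per gene set: coverage (quantified/assigned), percent of
#' quantified members called down (D%) and up (U%), WPR, and the
#' pathway-level control change
#' 100 * (mean REC_L / mean REC_N - 1) over the quantified members (when
#' derived statistics are available for both conditions).
#'
#' @param sets list of [gene_set()] objects.
#' @param regulation output of [regulation_table()].
#' @param derived optional row-bound [derived_stats()] for both conditions.
#' @param ref,exp condition labels used in `derived`.
#' @return data.frame with columns `set`, `kegg_id`, `genes`
#'   (quantified/assigned), `n_quantified`, `n_assigned`, `d_pct`, `u_pct`,
#'   `wpr`, `delta_rec_pct`.
#' @export
pathway_summary <- function(sets, regulation, derived = NULL,
                            ref = "N", exp = "L") {
  rows <- lapply(sets, function(s) {
    members <- regulation[regulation$gene %in% s$genes, , drop = FALSE]
    nq <- nrow(members)
    if (nq == 0) stop("no quantified members in gene set '", s$name, "'")
    delta_rec_pct <- NA_real_
    if (!is.null(derived)) {
      dn <- derived[derived$condition == ref &
                    derived$gene %in% s$genes, , drop = FALSE]
      dl <- derived[derived$condition == exp &
                    derived$gene %in% s$genes, , drop = FALSE]
      if (nrow(dn) > 0 && nrow(dl) > 0) {
        delta_rec_pct <- 100 * (mean(dl$rec) / mean(dn$rec) - 1)
      }
    }
    data.frame(
      set = s$name, kegg_id = s$kegg_id,
      genes = paste0(nq, "/", length(s$genes)),
      n_quantified = nq, n_assigned = length(s$genes),
      d_pct = 100 * sum(members$call == "down") / nq,
      u_pct = 100 * sum(members$call == "up") / nq,
      wpr = compute_wpr(members$wir),
      delta_rec_pct = delta_rec_pct,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Export a coordination network as SIF edges plus node annotations
#'
#' Edges are the significant pairs (synergistic as `"syn"`, antagonistic as
#' `"ant"`, and optionally independent as `"ind"`); node annotations carry
#' each gene's regulation call, mirroring the red/green/yellow node coding
#' of fabric network figures.
#'
#' @param pairs pair table from [pair_stats()] (one condition).
#' @param regulation output of [regulation_table()] (for node calls);
#'   genes absent from it are annotated `"none"`.
#' @param sif_path,nodes_path output file paths (skipped when `NULL`).
#' @param include_independent also export independent pairs as `"ind"`
#'   edges (default `FALSE`).
#' @return list with `edges` and `nodes` data.frames, invisibly when
#'   writing, visibly otherwise.
#' @export
export_fabric_network <- function(pairs, regulation = NULL,
                                  sif_path = NULL, nodes_path = NULL,
                                  include_independent = FALSE) {
  keep <- pairs$cls %in% c("synergistic", "antagonistic",
                           if (include_independent) "independent")
  edges <- data.frame(
    gene_i = pairs$gene_i[keep],
    cls = c(synergistic = "syn", antagonistic = "ant",
            independent = "ind")[pairs$cls[keep]],
    gene_j = pairs$gene_j[keep],
    stringsAsFactors = FALSE, row.names = NULL
  )
  genes <- unique(c(pairs$gene_i, pairs$gene_j))
  call <- rep("none", length(genes))
  if (!is.null(regulation)) {
    idx <- match(genes, regulation$gene)
    call[!is.na(idx)] <- regulation$call[idx[!is.na(idx)]]
  }
  nodes <- data.frame(gene = genes, call = call, stringsAsFactors = FALSE)
  if (!is.null(sif_path)) write_sif(edges, sif_path)
  if (!is.null(nodes_path)) write_result_table(nodes, nodes_path)
  res <- list(edges = edges, nodes = nodes)
  if (is.null(sif_path) && is.null(nodes_path)) res else invisible(res)
}
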