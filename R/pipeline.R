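#' Run the full fabric analysis pipeline
#'
#' One-call orchestration from a configuration to every result table:
#' primary gene statistics, pair classifications (restricted by default to
#' the configured gene sets plus named anchor genes, because the full
#' transcriptome has N*(N-1)/2 pairs), derived statistics, the regulation
#' table with the fixed-1.5x comparison, pathway summaries, intra- and
#' inter-pathway coupling with remodeling ratios, and SIF networks. A run
#' manifest with input digests and output paths makes reruns verifiable:
#' identical configuration and inputs give bit-identical outputs.
#'
#' @param config either the path to a YAML file or a list with entries:
#'   \describe{
#'     \item{expression}{path to the expression TSV (see
#'       [read_expression_table()]).}
#'     \item{design}{named list condition -> replicate column names.}
#'     \item{gene_sets}{optional path to a GMT file.}
#'     \item{anchors}{optional character vector of anchor genes whose pairs
#'       against all dataset genes are computed.}
#'     \item{all_pairs}{logical, compute every distinct gene pair
#'       (default `FALSE`; quadratic in gene count).}
#'     \item{alpha, independence_threshold, cv_correction, gch_exponent,
#'       seed}{analysis parameters, see [fabric_config()].}
#'     \item{out_dir}{output directory (created if missing).}
#'   }
#' @return invisibly, a list with the in-memory tables (`stats`, `pairs`,
#'   `derived`, `regulation`, `pathways`, `coupling`) and the `manifest`.
#' @export
run_gfp <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- fabric_config(
    alpha = config$alpha %||% 0.05,
    independence_threshold = config$independence_threshold %||% 0.05,
    cv_correction = config$cv_correction %||% TRUE,
    gch_exponent = config$gch_exponent %||% 4,
    seed = config$seed %||% 1L
  )
  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(cfg$seed)

  design <- lapply(config$design, unlist)
  dataset <- read_expression_table(config$expression, design)
  conditions <- dataset$conditions
  sets <- if (!is.null(config$gene_sets)) read_gmt(config$gene_sets) else
    list()

  stats <- gene_stats(dataset, cfg)

  # pair scope: every configured set's genes plus anchors, or all genes
  scope <- if (isTRUE(config$all_pairs)) quantified_genes(dataset) else {
    unique(c(unlist(lapply(sets, `[[`, "genes")),
             unlist(config$anchors)))
  }
  scope <- intersect(scope, quantified_genes(dataset))
  if (length(scope) < 2) {
    stop("pipeline stage 'pairs': fewer than 2 quantified genes in scope; ",
         "configure gene_sets, anchors, or all_pairs")
  }
  pairs <- do.call(rbind, lapply(conditions, function(cond) {
    pair_stats(dataset, scope, condition = cond, config = cfg)
  }))

  derived <- do.call(rbind, lapply(conditions, function(cond) {
    derived_stats(stats, pairs[pairs$condition == cond, ], cfg)
  }))

  regulation <- regulation_table(dataset, cfg, stats = stats,
                                 derived = derived,
                                 ref = conditions[[1]],
                                 exp = conditions[[2]])
  regulation <- compare_fixed_cutoff(regulation, alpha = cfg$alpha)

  pathways <- NULL
  coupling <- NULL
  if (length(sets) > 0) {
    pathways <- pathway_summary(sets, regulation, derived,
                                ref = conditions[[1]],
                                exp = conditions[[2]])
    rows <- list()
    for (cond in conditions) {
      pc <- pairs[pairs$condition == cond, ]
      for (s in sets) {
        nq <- length(intersect(s$genes, quantified_genes(dataset)))
        if (nq >= 2) rows[[length(rows) + 1]] <-
            intra_pathway_coord(pc, s, cond)
      }
      if (length(sets) >= 2) {
        combs <- utils::combn(length(sets), 2)
        for (k in seq_len(ncol(combs))) {
          rows[[length(rows) + 1]] <- inter_pathway_coord(
            pc, sets[[combs[1, k]]], sets[[combs[2, k]]], cond)
        }
      }
    }
    coupling <- do.call(rbind, rows)
    rownames(coupling) <- NULL
    # remodeling of each coupling between the two conditions
    key <- paste(coupling$set_a, coupling$set_b)
    cn <- coupling[coupling$condition == conditions[[1]], ]
    cl <- coupling[coupling$condition == conditions[[2]], ]
    idx <- match(paste(cn$set_a, cn$set_b), paste(cl$set_a, cl$set_b))
    remodeling <- vapply(seq_len(nrow(cn)), function(i) {
      if (is.na(idx[i]) || cn$coord[i] == 0 || cl$coord[idx[i]] == 0) {
        NA_real_
      } else remodeling_ratio(cn$coord[i], cl$coord[idx[i]])
    }, numeric(1))
    coupling$remodeling <- NA_real_
    coupling$remodeling[coupling$condition == conditions[[1]]] <- remodeling
  }

  paths <- list(
    gene_stats = file.path(out_dir, "gene_stats.tsv"),
    pairs = file.path(out_dir, "pairs.tsv"),
    derived = file.path(out_dir, "derived_stats.tsv"),
    regulation = file.path(out_dir, "regulation.tsv"),
    manifest = file.path(out_dir, "manifest.yaml")
  )
  write_result_table(stats, paths$gene_stats)
  write_result_table(pairs, paths$pairs)
  write_result_table(derived, paths$derived)
  write_result_table(regulation, paths$regulation)
  if (!is.null(pathways)) {
    paths$pathways <- file.path(out_dir, "pathway_summary.tsv")
    write_result_table(pathways, paths$pathways)
  }
  if (!is.null(coupling)) {
    paths$coupling <- file.path(out_dir, "coupling.tsv")
    write_result_table(coupling, paths$coupling)
  }
  for (cond in conditions) {
    paths[[paste0("network_", cond)]] <-
      file.path(out_dir, paste0("network_", cond, ".sif"))
    paths[[paste0("nodes_", cond)]] <-
      file.path(out_dir, paste0("nodes_", cond, ".tsv"))
    export_fabric_network(pairs[pairs$condition == cond, ], regulation,
                          sif_path = paths[[paste0("network_", cond)]],
                          nodes_path = paths[[paste0("nodes_", cond)]])
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("genefabric")),
    seed = cfg$seed,
    config_digest = digest_object(config),
    input_digests = list(
      expression = unname(tools::md5sum(config$expression)),
      gene_sets = if (!is.null(config$gene_sets))
        unname(tools::md5sum(config$gene_sets)) else NULL
    ),
    counts = list(
      quantified_genes = length(quantified_genes(dataset)),
      spots_dropped = dataset$n_dropped,
      up = sum(regulation$call == "up"),
      down = sum(regulation$call == "down"),
      falsely_up = sum(regulation$category == "falsely_up"),
      falsely_down = sum(regulation$category == "falsely_down"),
      missed_up = sum(regulation$category == "missed_up"),
      missed_down = sum(regulation$category == "missed_down")
    ),
    outputs = lapply(paths, normalizePath, mustWork = FALSE)
  )
  yaml::write_yaml(manifest, paths$manifest)

  invisible(list(dataset = dataset, stats = stats, pairs = pairs,
                 derived = derived, regulation = regulation,
                 pathways = pathways, coupling = coupling,
                 manifest = manifest))
}

# md5 digest of an arbitrary R object via its canonical serialization
digest_object <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(x, tmp, version = 2, compress = FALSE)
  unname(tools::md5sum(tmp))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
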