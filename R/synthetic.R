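#' Specification of a synthetic expression fabric
#'
#' Describes a two-condition microarray-like experiment with known ground
#' truth: log-normal baseline expression levels, per-gene coefficients of
#' variation, correlation blocks (co-regulated gene groups with synergistic
#' or antagonistic members), redundant probing spots, and a designated set
#' of genes with imposed fold-changes.
#'
#' @param n_genes number of genes.
#' @param n_replicates biological replicates per condition (default 4, the
#'   study design emulated).
#' @param spot_probs probabilities of a gene being probed by 1, 2, or 3
#'   redundant spots (default `c(0.6, 0.3, 0.1)`).
#' @param blocks list of blocks, each a list with `genes` (integer indices),
#'   `rho` (within-block correlation magnitude, `|rho| < 1`), and optional
#'   `sign` (vector of +1/-1 per member; -1 members are anti-correlated
#'   with the block, giving antagonistic pairs). Blocks must be disjoint.
#' @param ave_meanlog,ave_sdlog log-normal parameters of the baseline AVE
#'   (defaults 0 and 2: a median-normalized transcriptome whose top genes
#'   reach the 10^3 scale).
#' @param cv_range range of true per-gene CVs, drawn log-uniformly
#'   (default `c(0.01, 1)`, i.e. 1-100%).
#' @param fold named numeric vector: true fold-change of each regulated
#'   gene (names are gene labels `g1`, `g2`, ...; values > 0, applied
#'   multiplicatively in the experimental condition). Unlisted genes have
#'   fold 1.
#' @param ave,cv optional named numeric vectors imposing exact baseline
#'   AVEs / true CVs on specific genes (same `g<i>` labels), overriding the
#'   sampled values; used to plant known ground truth.
#' @param spot_noise_frac spot-level noise SD as a fraction of the gene's
#'   replicate-level CV (default 0.2).
#' @param seed integer seed; the whole generation is deterministic given it.
#' @return object of class `fabric_spec`.
#' @export
fabric_spec <- function(n_genes, n_replicates = 4,
                        spot_probs = c(0.6, 0.3, 0.1),
                        blocks = list(),
                        ave_meanlog = 0, ave_sdlog = 2,
                        cv_range = c(0.01, 1),
                        fold = numeric(),
                        ave = numeric(), cv = numeric(),
                        spot_noise_frac = 0.2,
                        seed = 1L) {
  stopifnot(n_genes >= 2, n_replicates >= 2,
            length(spot_probs) == 3, all(spot_probs >= 0),
            cv_range[1] > 0, cv_range[2] >= cv_range[1],
            all(fold > 0), all(ave > 0), all(cv > 0),
            spot_noise_frac >= 0)
  used <- integer()
  for (b in blocks) {
    stopifnot(abs(b$rho) < 1, all(b$genes >= 1), all(b$genes <= n_genes))
    if (length(intersect(used, b$genes)) > 0) {
      stop("correlation blocks must be disjoint")
    }
    if (!is.null(b$sign)) stopifnot(length(b$sign) == length(b$genes),
                                    all(b$sign %in% c(-1, 1)))
    used <- c(used, b$genes)
  }
  structure(
    list(n_genes = as.integer(n_genes),
         n_replicates = as.integer(n_replicates),
         spot_probs = spot_probs / sum(spot_probs),
         blocks = blocks,
         ave_meanlog = ave_meanlog, ave_sdlog = ave_sdlog,
         cv_range = cv_range, fold = fold,
         ave = ave, cv = cv,
         spot_noise_frac = spot_noise_frac,
         seed = as.integer(seed)),
    class = "fabric_spec"
  )
}

#' Generate a synthetic two-condition dataset with ground truth
#'
#' For every condition and replicate, each correlation block draws a latent
#' standard-normal factor f; gene i's replicate value is
#' `AVE * (1 + CV * (l*f + sqrt(1 - l^2)*e))` with loading `l = sign *
#' sqrt(rho)` (so two same-sign block members correlate at +rho, opposite
#' signs at -rho) and e an independent standard normal. Genes outside any
#' block are pure noise. The experimental-condition AVE is the baseline
#' times the gene's true fold. Redundant spots share the replicate value
#' plus small multiplicative spot noise; a single-spot gene's spot is the
#' replicate measurement itself and carries no extra jitter, so imposed
#' CVs and pair correlations are exact at the observable level for
#' single-spot genes. Values are clipped at a floor of
#' 1e-6 times the median baseline AVE (clipping probability is negligible
#' for CVs up to ~33%).
#'
#' @param spec a [fabric_spec()].
#' @param conditions condition labels (default `c("N", "L")`, reference
#'   first).
#' @return list with elements `dataset` (a [fabric_dataset()]) and `truth`
#'   (data.frame: `gene`, `ave_n`, `ave_l`, `cv`, `fold`, `block`,
#'   `block_sign`, `n_spots`).
#' @export
generate_fabric <- function(spec, conditions = c("N", "L")) {
  stopifnot(inherits(spec, "fabric_spec"), length(conditions) == 2)
  set.seed(spec$seed)
  ng <- spec$n_genes
  n <- spec$n_replicates
  genes <- paste0("g", seq_len(ng))

  n_spots <- sample(1:3, ng, replace = TRUE, prob = spec$spot_probs)
  ave_n <- stats::rlnorm(ng, spec$ave_meanlog, spec$ave_sdlog)
  cv <- exp(stats::runif(ng, log(spec$cv_range[1]), log(spec$cv_range[2])))
  names(ave_n) <- names(cv) <- genes
  override <- function(base, map, what) {
    unknown <- setdiff(names(map), genes)
    if (length(unknown) > 0) stop(what, " map names unknown genes")
    base[names(map)] <- map
    base
  }
  ave_n <- override(ave_n, spec$ave, "ave")
  cv <- override(cv, spec$cv, "cv")
  fold <- override(stats::setNames(rep(1, ng), genes), spec$fold, "fold")
  ave <- cbind(ave_n, ave_n * fold)
  colnames(ave) <- conditions

  loading <- rep(0, ng)
  block_id <- rep(NA_integer_, ng)
  block_sign <- rep(1, ng)
  for (bi in seq_along(spec$blocks)) {
    b <- spec$blocks[[bi]]
    sgn <- if (is.null(b$sign)) rep(1, length(b$genes)) else b$sign
    loading[b$genes] <- sgn * sqrt(abs(b$rho))
    block_id[b$genes] <- bi
    block_sign[b$genes] <- sgn
  }

  floor_val <- 1e-6 * stats::median(ave_n)
  spot_gene <- rep(seq_len(ng), times = n_spots)
  values <- lapply(conditions, function(cond) {
    m <- matrix(0, nrow = length(spot_gene), ncol = n)
    for (r in seq_len(n)) {
      f <- stats::rnorm(length(spec$blocks))
      eps <- stats::rnorm(ng)
      z <- ifelse(is.na(block_id), eps,
                  loading * f[ifelse(is.na(block_id), 1, block_id)] +
                    sqrt(1 - loading^2) * eps)
      rep_val <- ave[, cond] * (1 + cv * z)
      spot_eps <- stats::rnorm(length(spot_gene))
      # jitter only differentiates redundant spots; a gene's sole spot IS
      # the replicate measurement and carries no extra noise
      jitter <- (n_spots[spot_gene] >= 2) *
        spec$spot_noise_frac * cv[spot_gene] * spot_eps
      sv <- rep_val[spot_gene] * (1 + jitter)
      m[, r] <- pmax(sv, floor_val)
    }
    m
  })
  names(values) <- conditions

  ds <- fabric_dataset(
    spot_id = paste0("s", seq_along(spot_gene)),
    gene = genes[spot_gene],
    values = values,
    conditions = conditions
  )
  truth <- data.frame(
    gene = genes, ave_n = ave[, 1], ave_l = ave[, 2], cv = cv,
    fold = fold, block = block_id, block_sign = block_sign,
    n_spots = n_spots, stringsAsFactors = FALSE, row.names = NULL
  )
  list(dataset = ds, truth = truth)
}

#' Expected regulation calls and pair classes from generator ground truth
#'
#' Converts true generator parameters into the calls an ideal analysis
#' would make: the analytic REV is `100 * CV * c(nu)` (chi-square
#' correction for the gene's pooled degrees of freedom), the analytic CUT
#' follows from the two REVs, and a gene is expected up/down when its true
#' fold clears that CUT. Within-block pairs are expected synergistic
#' (same-sign members) or antagonistic (opposite signs) when `rho` is
#' large; cross-block and out-of-block pairs are expected independent or
#' unclassified.
#'
#' @param truth the `truth` data.frame from [generate_fabric()].
#' @param spec the generating [fabric_spec()].
#' @param cv_correction apply the chi-square correction in the analytic
#'   REV (default `TRUE`, matching the default analysis).
#' @return list with `genes` (data.frame: `gene`, `rev_true`, `cut_true`,
#'   `expected_call`) and `pairs` (data.frame: `gene_i`, `gene_j`,
#'   `expected_cls` among `"synergistic"`, `"antagonistic"`,
#'   `"independent_or_unclassified"` for within-block pairs and all other
#'   pairs respectively).
#' @export
truth_table <- function(truth, spec, cv_correction = TRUE) {
  nu <- truth$n_spots * (spec$n_replicates - 1)
  cc <- if (cv_correction) {
    vapply(nu, rev_correction_factor, numeric(1))
  } else rep(1, nrow(truth))
  rev_true <- 100 * truth$cv * cc
  cut_true <- compute_cut(rev_true, rev_true)   # same true CV both sides
  x_true <- ifelse(truth$fold >= 1, truth$fold, -1 / truth$fold)
  expected_call <- ifelse(x_true >= cut_true, "up",
                   ifelse(x_true <= -cut_true, "down", "none"))
  genes <- data.frame(gene = truth$gene, rev_true = rev_true,
                      cut_true = cut_true, expected_call = expected_call,
                      stringsAsFactors = FALSE)
  pair_rows <- list()
  for (bi in seq_along(spec$blocks)) {
    b <- spec$blocks[[bi]]
    if (length(b$genes) < 2) next
    sgn <- if (is.null(b$sign)) rep(1, length(b$genes)) else b$sign
    idx <- utils::combn(length(b$genes), 2)
    pair_rows[[bi]] <- data.frame(
      gene_i = truth$gene[b$genes[idx[1, ]]],
      gene_j = truth$gene[b$genes[idx[2, ]]],
      expected_cls = ifelse(abs(b$rho) < 0.5, "independent_or_unclassified",
                     ifelse(sgn[idx[1, ]] * sgn[idx[2, ]] > 0,
                            "synergistic", "antagonistic")),
      stringsAsFactors = FALSE)
  }
  pairs <- if (length(pair_rows) > 0) do.call(rbind, pair_rows) else
    data.frame(gene_i = character(), gene_j = character(),
               expected_cls = character(), stringsAsFactors = FALSE)
  rownames(pairs) <- NULL
  list(genes = genes, pairs = pairs)
}
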