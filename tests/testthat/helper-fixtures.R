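# Shared fixture builders: everything is constructed in code at test time.

# Minimal hand-built dataset: values chosen, not sampled.
make_tiny_dataset <- function() {
  fabric_dataset(
    spot_id = paste0("s", 1:4),
    gene = c("A", "A", "B", "C"),
    values = list(
      N = matrix(c(
        2, 2, 2, 2,        # A spot 1
        9, 10, 11, 10,     # A spot 2
        1, 2, 3, 4,        # B
        4, 3, 2, 1         # C (anti-phase with B)
      ), nrow = 4, byrow = TRUE),
      L = matrix(c(
        4, 4, 4, 4,
        20, 19, 21, 20,
        2, 4, 6, 8,
        8, 6, 4, 2
      ), nrow = 4, byrow = TRUE)
    ),
    conditions = c("N", "L")
  )
}

# Write a 6-row expression TSV with the given extra rows appended.
write_expression_fixture <- function(path, extra_lines = character()) {
  header <- paste(c("spot", "gene", paste0("N", 1:4), paste0("L", 1:4)),
                  collapse = "\t")
  rows <- vapply(1:6, function(i) {
    paste(c(paste0("s", i), paste0("G", ceiling(i / 2)),
            round(i + (1:4) / 10, 3), round(2 * i + (1:4) / 10, 3)),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, rows, extra_lines), path)
  path
}

default_design <- function() {
  list(N = paste0("N", 1:4), L = paste0("L", 1:4))
}

# Synthetic pair table with exact class counts among `genes`,
# classes assigned to the first pairs in combn order.
make_pair_table <- function(genes, n_syn, n_ant, n_ind,
                            condition = "N", genes_b = NULL) {
  if (is.null(genes_b)) {
    idx <- utils::combn(length(genes), 2)
    gi <- genes[idx[1, ]]
    gj <- genes[idx[2, ]]
  } else {
    grid <- expand.grid(gene_i = genes, gene_j = genes_b,
                        stringsAsFactors = FALSE)
    grid <- grid[grid$gene_i != grid$gene_j, ]
    key <- ifelse(grid$gene_i < grid$gene_j,
                  paste(grid$gene_i, grid$gene_j),
                  paste(grid$gene_j, grid$gene_i))
    grid <- grid[!duplicated(key), ]
    gi <- grid$gene_i
    gj <- grid$gene_j
  }
  np <- length(gi)
  stopifnot(n_syn + n_ant + n_ind <= np)
  cls <- rep("unclassified", np)
  cls[seq_len(n_syn)] <- "synergistic"
  if (n_ant > 0) cls[n_syn + seq_len(n_ant)] <- "antagonistic"
  if (n_ind > 0) cls[n_syn + n_ant + seq_len(n_ind)] <- "independent"
  cor <- ifelse(cls == "synergistic", 0.99,
         ifelse(cls == "antagonistic", -0.99,
         ifelse(cls == "independent", 0.01, 0.5)))
  data.frame(gene_i = gi, gene_j = gj, condition = condition,
             cor = cor, n_points = 4L, cls = cls,
             stringsAsFactors = FALSE)
}

# Independent Welch t-test oracle (statistic + Satterthwaite df by hand).
welch_oracle <- function(a, b) {
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  2 * stats::pt(-abs(t), df)
}
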