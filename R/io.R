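#' Read a replicate-level expression table
#'
#' Expects a tab-separated file with a header. Two columns identify the spot
#' and its gene symbol; the remaining columns carry normalized intensities
#' for the replicates of each condition, matched by a design map (never by
#' column order). Rows with any missing or non-positive intensity in either
#' condition are dropped and counted, one spot at a time, mirroring the
#' quality elimination of corrupted or low-signal spots; other spots of the
#' same gene survive. Genes left without any spot disappear from the
#' analysis.
#'
#' @param path path to the TSV file.
#' @param design named list mapping each condition label to the character
#'   vector of its replicate column names, e.g.
#'   `list(N = c("N1","N2","N3","N4"), L = c("L1","L2","L3","L4"))`.
#' @param spot_col,gene_col names of the spot-identifier and gene-symbol
#'   columns (defaults `"spot"` and `"gene"`).
#' @return a [fabric_dataset()]; the number of eliminated spots is available
#'   as `$n_dropped`.
#' @export
read_expression_table <- function(path, design,
                                  spot_col = "spot", gene_col = "gene") {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  for (col in c(spot_col, gene_col)) {
    if (!col %in% names(tab)) stop("missing column: ", col)
  }
  for (cond in names(design)) {
    missing <- setdiff(design[[cond]], names(tab))
    if (length(missing) > 0) {
      stop("condition '", cond, "' is missing replicate column(s): ",
           paste(missing, collapse = ", "))
    }
    if (length(design[[cond]]) < 2) {
      stop("condition '", cond, "' needs >= 2 replicate columns")
    }
  }
  values <- lapply(design, function(cols) {
    m <- as.matrix(tab[, cols, drop = FALSE])
    storage.mode(m) <- "double"
    m
  })
  drop_bad_spots(tab[[spot_col]], tab[[gene_col]], values,
                 conditions = names(design))$dataset
}

#' Write a dataset back to the expression-table format
#'
#' Inverse of [read_expression_table()]; round-trips bit-exactly through
#' R's full-precision decimal formatting.
#'
#' @param dataset a [fabric_dataset()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(dataset, path) {
  mats <- lapply(dataset$conditions, function(cond) {
    m <- dataset$values[[cond]]
    colnames(m) <- paste0(cond, seq_len(ncol(m)))
    m
  })
  out <- data.frame(spot = dataset$spot_id, gene = dataset$gene,
                    do.call(cbind, mats), check.names = FALSE,
                    stringsAsFactors = FALSE)
  write_result_table(out, path)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT dialect: one set per line; tab-separated fields are the set
#' name, a description (here used for the pathway identifier, e.g. a KEGG
#' id), then the member gene symbols. Duplicate symbols within a line are
#' deduplicated; sets may overlap freely across lines.
#'
#' @param path path to the GMT file.
#' @return named list of objects of class `gene_set`, each a list with
#'   `name`, `kegg_id`, and `genes` (unique character vector).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(seq_along(lines), function(i) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stop("GMT parse error at line ", i, ": need name, description, ",
           "and at least one gene")
    }
    genes <- unique(fields[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0) stop("GMT parse error at line ", i,
                                 ": empty gene list")
    gene_set(fields[[1]], fields[[2]], genes)
  })
  names(sets) <- vapply(sets, `[[`, character(1), "name")
  sets
}

#' Construct a gene set
#'
#' @param name short set label (e.g. `"GLY"`).
#' @param kegg_id pathway identifier (e.g. `"mmu00010"`); free-form.
#' @param genes character vector of member symbols; deduplicated.
#' @return object of class `gene_set`.
#' @export
gene_set <- function(name, kegg_id = "", genes = character()) {
  genes <- unique(as.character(genes))
  if (length(genes) == 0) stop("gene set '", name, "' is empty")
  structure(list(name = name, kegg_id = kegg_id, genes = genes),
            class = "gene_set")
}

#' Write gene sets to GMT
#' @param sets list of [gene_set()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(sets, function(s) {
    paste(c(s$name, s$kegg_id, s$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a result table as TSV
#'
#' All result tables of the package (gene-, pair-, and pathway-level) go
#' through this writer; numeric columns keep full precision so read/write
#' round-trips are lossless.
#'
#' @param x data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_result_table <- function(x, path) {
  utils::write.table(format(x, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a result table written by [write_result_table()]
#' @param path path to the TSV file.
#' @return data.frame.
#' @export
read_result_table <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
}

#' Write a coordination network as a SIF edge list
#'
#' One edge per line: `gene_i <TAB> class <TAB> gene_j`, the interchange
#' format understood by Cytoscape and igraph importers.
#'
#' @param edges data.frame with columns `gene_i`, `cls`, `gene_j`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sif <- function(edges, path) {
  writeLines(paste(edges$gene_i, edges$cls, edges$gene_j, sep = "\t"), path)
  invisible(path)
}

#' Read a SIF edge list
#' @param path path to the SIF file.
#' @return data.frame with columns `gene_i`, `cls`, `gene_j`.
#' @export
read_sif <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(data.frame(gene_i = character(), cls = character(),
                      gene_j = character(), stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  data.frame(
    gene_i = vapply(parts, `[[`, character(1), 1),
    cls = vapply(parts, `[[`, character(1), 2),
    gene_j = vapply(parts, `[[`, character(1), 3),
    stringsAsFactors = FALSE
  )
}
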