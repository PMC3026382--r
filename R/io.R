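#' Construct a two-phenotype expression set
#'
#' The in-memory container used throughout the package: a genes x samples
#' numeric matrix plus a phenotype label (1 or 2) per sample. Both classes
#' must carry at least two samples so that class-conditional variances can be
#' estimated.
#'
#' @param values Numeric matrix, genes in rows (rownames = gene identifiers),
#'   samples in columns (colnames = sample identifiers).
#' @param labels Integer-like vector of phenotype labels in `{1, 2}`, one per
#'   column of `values`; may be named by sample identifier.
#' @return An object of class `"expression_set"`: a list with elements
#'   `values` and `labels`.
#' @export
expression_set <- function(values, labels) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix (genes x samples)")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must carry gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicated gene identifiers in expression matrix: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicated sample identifiers in expression matrix")
  labels <- as.integer(labels)
  if (length(labels) != ncol(values))
    stop("one label per sample required: got ", length(labels), " labels for ",
         ncol(values), " samples")
  if (!all(labels %in% c(1L, 2L)))
    stop("phenotype labels must be 1 or 2")
  if (sum(labels == 1L) < 2L || sum(labels == 2L) < 2L)
    stop("each phenotype class needs at least 2 samples")
  names(labels) <- colnames(values)
  structure(list(values = values, labels = labels), class = "expression_set")
}

#' @export
print.expression_set <- function(x, ...) {
  cat(sprintf("expression_set: %d genes x %d samples (class 1: %d, class 2: %d)\n",
              nrow(x$values), ncol(x$values),
              sum(x$labels == 1L), sum(x$labels == 2L)))
  invisible(x)
}

#' Read an expression matrix and phenotype labels from TSV files
#'
#' The matrix file is tab-separated with a header row of sample identifiers
#' and one row per gene (first column = gene identifier). The labels file has
#' two tab-separated columns: sample identifier and phenotype (1 or 2), no
#' header. Samples present in the matrix but missing from the labels file are
#' dropped with a warning.
#'
#' @param matrix_path Path to the expression TSV.
#' @param labels_path Path to the labels TSV.
#' @return An [expression_set()].
#' @export
read_expression <- function(matrix_path, labels_path) {
  raw <- utils::read.table(matrix_path, header = TRUE, sep = "\t",
                           row.names = NULL, check.names = FALSE,
                           colClasses = "character", quote = "")
  if (ncol(raw) < 2L) stop("expression file needs a gene column and >= 1 sample")
  gene_ids <- raw[[1L]]
  num <- as.matrix(raw[, -1L, drop = FALSE])
  vals <- suppressWarnings(matrix(as.numeric(num), nrow = nrow(num),
                                  dimnames = list(gene_ids, colnames(num))))
  if (anyNA(vals)) {
    bad <- which(is.na(vals) & !toupper(num) %in% c("NA", ""), arr.ind = TRUE)
    if (nrow(bad) > 0L)
      stop(sprintf("malformed numeric cell at gene '%s', sample '%s'",
                   gene_ids[bad[1L, 1L]], colnames(num)[bad[1L, 2L]]))
  }
  lab <- utils::read.table(labels_path, header = FALSE, sep = "\t",
                           colClasses = "character", quote = "")
  if (ncol(lab) < 2L) stop("labels file must have two columns: sample, phenotype")
  lab_map <- lab[[2L]]
  names(lab_map) <- lab[[1L]]
  keep <- colnames(vals) %in% names(lab_map)
  if (!all(keep)) {
    warning(sum(!keep), " sample(s) absent from the labels file were dropped: ",
            paste(utils::head(colnames(vals)[!keep], 5L), collapse = ", "))
    vals <- vals[, keep, drop = FALSE]
  }
  labels <- suppressWarnings(as.integer(lab_map[colnames(vals)]))
  if (anyNA(labels) || !all(labels %in% c(1L, 2L)))
    stop("phenotype labels must be 1 or 2")
  expression_set(vals, labels)
}

#' Read an undirected PPI network
#'
#' Supports a plain two-column tab- or space-separated edge list and the
#' Cytoscape SIF dialect (`nodeA <relation> nodeB`; the relation column is
#' ignored). Duplicate edges (in either orientation) are collapsed and
#' self-loops discarded with a message.
#'
#' @param path Path to the network file.
#' @param dialect `"edge_list"` or `"sif"`.
#' @return An undirected simple [igraph::graph] whose vertex `name` attribute
#'   holds the protein/gene identifiers.
#' @export
read_network <- function(path, dialect = c("edge_list", "sif")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    return(igraph::make_empty_graph(0, directed = FALSE))
  fields <- strsplit(trimws(lines), "[ \t]+")
  need <- if (dialect == "edge_list") 2L else 3L
  short <- which(vapply(fields, length, 1L) < need)
  if (length(short) > 0L)
    stop(sprintf("line %d of '%s': expected %d columns", short[1L], path, need))
  a <- vapply(fields, `[[`, "", 1L)
  b <- vapply(fields, `[[`, "", need)
  loops <- a == b
  if (any(loops)) message("discarded ", sum(loops), " self-loop(s)")
  a <- a[!loops]; b <- b[!loops]
  g <- igraph::graph_from_edgelist(cbind(a, b), directed = FALSE)
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Restrict a network to the genes measured in an expression set
#'
#' Returns the induced subgraph on the intersection of network nodes and
#' expression gene identifiers, keeping all edges among them. Nodes isolated
#' by the restriction are retained.
#'
#' @param network An undirected igraph.
#' @param expression An [expression_set()].
#' @return The induced igraph subgraph.
#' @export
induce_network <- function(network, expression) {
  common <- intersect(igraph::V(network)$name, rownames(expression$values))
  if (length(common) == 0L)
    stop("no network node is present in the expression data; nothing to search")
  igraph::induced_subgraph(network, common)
}

#' Write an ordered marker list in GMT format
#'
#' One line per marker: name (`marker_001`, ...), a description field carrying
#' the discriminative power R formatted to 4 decimals, then the member gene
#' identifiers, all tab-separated. Marker order is preserved (rank order).
#'
#' @param markers A `marker_set` fit or a list of marker records, each with
#'   elements `members` (character) and `R` (numeric).
#' @param path Output file path.
#' @export
write_markers_gmt <- function(markers, path) {
  if (inherits(markers, "marker_set")) markers <- markers$markers
  if (length(markers) == 0L) stop("empty marker list")
  lines <- vapply(seq_along(markers), function(i) {
    m <- markers[[i]]
    paste(c(sprintf("marker_%03d", i), sprintf("R=%.4f", m$R), m$members),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' @param path Path to a GMT file (name, description, member genes per line).
#' @return A named list of character vectors of gene identifiers.
#' @export
read_markers_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, 1L) < 3L)
  if (length(bad) > 0L)
    stop(sprintf("line %d of '%s': a GMT line needs name, description and >= 1 gene",
                 bad[1L], path))
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- vapply(fields, `[[`, "", 1L)
  sets
}

#' Write an undirected network as a two-column edge list
#'
#' @param network An igraph.
#' @param path Output file path.
#' @export
write_network <- function(network, path) {
  el <- igraph::as_edgelist(network, names = TRUE)
  utils::write.table(el, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write an expression set as matrix + labels TSV files
#'
#' @param expression An [expression_set()].
#' @param matrix_path,labels_path Output paths.
#' @export
write_expression <- function(expression, matrix_path, labels_path) {
  df <- data.frame(gene = rownames(expression$values),
                   expression$values, check.names = FALSE)
  utils::write.table(df, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    data.frame(sample = names(expression$labels),
               phenotype = expression$labels),
    labels_path, sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  invisible(matrix_path)
}
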