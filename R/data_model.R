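#' Construct and validate a sample design table
#'
#' The design describes a short longitudinal culture experiment: each sample
#' is one RNA-seq library from one patient, in one culture condition
#' (`autologous` PBMC culture or CLL-cell `monoculture`), at one day of the
#' time course, for one technical replicate.
#'
#' @param sample_id character vector of unique sample identifiers.
#' @param patient character vector of patient identifiers.
#' @param condition character vector, each `"autologous"` or `"monoculture"`.
#' @param day integer vector of days since culture start.
#' @param replicate integer vector of replicate indices.
#' @return a `data.frame` of class `sample_design`.
#' @export
sample_design <- function(sample_id, patient, condition, day, replicate) {
  d <- data.frame(
    sample_id = as.character(sample_id),
    patient = as.character(patient),
    condition = as.character(condition),
    day = as.integer(day),
    replicate = as.integer(replicate),
    stringsAsFactors = FALSE
  )
  validate_design(d)
  class(d) <- c("sample_design", "data.frame")
  d
}

validate_design <- function(d) {
  req <- c("sample_id", "patient", "condition", "day", "replicate")
  miss <- setdiff(req, names(d))
  if (length(miss))
    stop("design is missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(d$sample_id))
    stop("duplicate sample_id in design: ",
         paste(unique(d$sample_id[duplicated(d$sample_id)]), collapse = ", "))
  bad <- setdiff(unique(d$condition), c("autologous", "monoculture"))
  if (length(bad))
    stop("condition must be 'autologous' or 'monoculture', got: ",
         paste(bad, collapse = ", "))
  invisible(d)
}

#' Construct an expression matrix with a layer tag
#'
#' A plain numeric gene-by-sample matrix tagged with the processing layer it
#' carries (`counts`, `normalised` or `standardised`). Counts must be
#' non-negative integers.
#'
#' @param values numeric matrix, genes in rows (rownames required), samples in
#'   columns (colnames required).
#' @param layer one of `"counts"`, `"normalised"`, `"standardised"`.
#' @return the matrix with a `layer` attribute.
#' @export
expression_matrix <- function(values,
                              layer = c("counts", "normalised", "standardised")) {
  layer <- match.arg(layer)
  if (!is.matrix(values) || !is.numeric(values))
    stop("values must be a numeric matrix")
  if ((nrow(values) > 0 && is.null(rownames(values))) ||
      (ncol(values) > 0 && is.null(colnames(values))))
    stop("values must carry gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (layer == "counts") {
    if (any(values < 0) || any(values != round(values)))
      stop("counts layer must hold non-negative integers")
  }
  attr(values, "layer") <- layer
  values
}

expr_layer <- function(x) {
  l <- attr(x, "layer")
  if (is.null(l)) NA_character_ else l
}

#' Construct a regulon table
#'
#' A regulon prior maps each transcription factor to its known target genes
#' with a regulation mode (+1 activation, -1 repression) and a confidence
#' weight in (0, 1]. Duplicated (tf, target) pairs are collapsed to one entry.
#'
#' @param tf,target character vectors.
#' @param mode numeric vector of +1/-1 (or `"A"`/`"I"`).
#' @param weight numeric vector in (0, 1]; defaults to 1.
#' @return a `data.frame` of class `regulon` with columns tf, target, mode,
#'   weight.
#' @export
regulon <- function(tf, target, mode, weight = 1) {
  if (is.character(mode))
    mode <- ifelse(mode == "A", 1, ifelse(mode == "I", -1, suppressWarnings(as.numeric(mode))))
  mode <- as.numeric(mode)
  if (any(is.na(mode)) || !all(mode %in% c(-1, 1)))
    stop("regulon mode must normalise to +1 or -1")
  weight <- rep_len(as.numeric(weight), length(tf))
  if (any(!is.finite(weight)) || any(weight <= 0) || any(weight > 1))
    stop("regulon weight must lie in (0, 1]")
  r <- data.frame(tf = as.character(tf), target = as.character(target),
                  mode = mode, weight = weight, stringsAsFactors = FALSE)
  r <- r[!duplicated(r[, c("tf", "target")]), , drop = FALSE]
  rownames(r) <- NULL
  if (nrow(r) == 0L) stop("empty regulon")
  class(r) <- c("regulon", "data.frame")
  r
}

#' Read an expression matrix and its sample design
#'
#' @param path TSV with gene ids in the first column and one column per
#'   sample.
#' @param design_path TSV with columns sample_id, patient, condition, day,
#'   replicate.
#' @param layer layer tag of the values on disk.
#' @return list with elements `expr` (matrix, see [expression_matrix()]) and
#'   `design` ([sample_design()]); matrix columns are aligned to the design
#'   row order.
#' @export
read_expression <- function(path, design_path, layer = "counts") {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  genes <- as.character(tab[[1L]])
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(vals)) stop("non-numeric cells in expression matrix ", path)
  rownames(vals) <- genes
  dd <- utils::read.delim(design_path, stringsAsFactors = FALSE)
  design <- sample_design(dd$sample_id, dd$patient, dd$condition, dd$day,
                          dd$replicate)
  missing_in_expr <- setdiff(design$sample_id, colnames(vals))
  if (length(missing_in_expr))
    stop("design samples absent from expression matrix: ",
         paste(missing_in_expr, collapse = ", "))
  extra <- setdiff(colnames(vals), design$sample_id)
  if (length(extra))
    stop("expression samples absent from design: ",
         paste(extra, collapse = ", "))
  vals <- vals[, design$sample_id, drop = FALSE]
  list(expr = expression_matrix(vals, layer), design = design)
}

#' Write an expression matrix (and optionally a design) to TSV
#'
#' Values are serialised with 17 significant digits so that a write/read
#' round trip is bit-exact.
#'
#' @param expr gene-by-sample matrix.
#' @param path output TSV path.
#' @param design optional [sample_design()] written next to the matrix.
#' @param design_path path for the design TSV (required when `design` given).
#' @export
write_expression <- function(expr, path, design = NULL, design_path = NULL) {
  df <- data.frame(gene_id = rownames(expr),
                   apply(expr, 2, function(col) formatC(col, digits = 17, format = "g")),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("gene_id", colnames(expr))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(design)) {
    if (is.null(design_path)) stop("design_path required when writing a design")
    utils::write.table(design, design_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read a regulon prior from TSV
#'
#' Expects columns `source` (TF), `target`, `mode` (+1/-1 or A/I) and an
#' optional `weight` column defaulting to 1 (confidence is often omitted in
#' curated regulon exports).
#'
#' @param path TSV path.
#' @return a [regulon()] table.
#' @export
read_regulon <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (nrow(tab) == 0L) stop("empty regulon file: ", path)
  req <- c("source", "target", "mode")
  miss <- setdiff(req, names(tab))
  if (length(miss))
    stop("regulon file missing columns: ", paste(miss, collapse = ", "))
  w <- if ("weight" %in% names(tab)) tab$weight else 1
  regulon(tab$source, tab$target, tab$mode, w)
}

#' Write a regulon to TSV
#' @param reg a [regulon()] table.
#' @param path output path.
#' @export
write_regulon <- function(reg, path) {
  out <- data.frame(source = reg$tf, target = reg$target, mode = reg$mode,
                    weight = reg$weight)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# canonical edge-table columns used by every network writer
canonical_edges <- function(net) {
  for (col in c("weight", "sign", "correlation", "provenance")) {
    if (is.null(net[[col]]))
      net[[col]] <- if (col == "provenance") NA_character_ else NA_real_
  }
  net[, c("source", "target", "weight", "sign", "correlation", "provenance"),
      drop = FALSE]
}

#' Write a network to disk
#'
#' Edge-TSV uses the fixed column set source, target, weight, sign,
#' correlation, provenance. GraphML (via igraph) additionally stores node
#' annotation attributes.
#'
#' @param net data.frame with at least `source` and `target` columns.
#' @param path output path.
#' @param format `"tsv"` or `"graphml"`.
#' @param directed logical flag stored with the graph.
#' @param node_attrs optional data.frame with a `name` column plus node
#'   attributes (e.g. condition/patient/time tags), used by GraphML.
#' @export
write_network <- function(net, path, format = c("tsv", "graphml"),
                          directed = TRUE, node_attrs = NULL) {
  format <- match.arg(format)
  edges <- canonical_edges(as.data.frame(net))
  if (format == "tsv") {
    num <- c("weight", "sign", "correlation")
    out <- edges
    for (col in num)
      out[[col]] <- ifelse(is.na(edges[[col]]), "NA",
                           formatC(edges[[col]], digits = 17, format = "g"))
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    verts <- unique(c(edges$source, edges$target,
                      if (!is.null(node_attrs)) node_attrs$name))
    vdf <- data.frame(name = verts, stringsAsFactors = FALSE)
    if (!is.null(node_attrs))
      vdf <- merge(vdf, node_attrs, by = "name", all.x = TRUE, sort = FALSE)
    g <- igraph::graph_from_data_frame(edges, directed = directed,
                                       vertices = vdf)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Read a network edge table written by [write_network()]
#' @param path file path.
#' @param format `"tsv"` or `"graphml"`.
#' @return for TSV, the canonical edge data.frame; for GraphML, a list with
#'   `edges` and `nodes` (node attribute data.frame).
#' @export
read_network <- function(path, format = c("tsv", "graphml")) {
  format <- match.arg(format)
  if (format == "tsv") {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                             colClasses = c(source = "character",
                                            target = "character",
                                            provenance = "character"))
    return(tab)
  }
  g <- igraph::read_graph(path, format = "graphml")
  list(edges = igraph::as_data_frame(g, what = "edges"),
       nodes = igraph::as_data_frame(g, what = "vertices"))
}
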