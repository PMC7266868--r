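#' Validate a sample sheet
#'
#' A sample sheet has one row per sequenced/assayed sample with columns
#' \code{sample_id}, \code{variety}, \code{condition} (\code{"control"} or
#' \code{"drought"}), \code{day} (non-negative integer) and \code{replicate}
#' (positive integer). Day-0 samples are the shared pre-treatment baseline:
#' they are listed once, under condition \code{"control"}, and belong to the
#' baseline of both groups (the drought time course starts from them).
#'
#' @param sheet data.frame to validate.
#' @return The validated sheet, invisibly usable downstream.
#' @export
validate_sample_sheet <- function(sheet) {
  need <- c("sample_id", "variety", "condition", "day", "replicate")
  miss <- setdiff(need, names(sheet))
  if (length(miss))
    dn_input_error("sample sheet missing column(s): %s",
                   paste(miss, collapse = ", "))
  if (anyDuplicated(sheet$sample_id))
    dn_input_error("duplicate sample_id: %s",
                   sheet$sample_id[duplicated(sheet$sample_id)][1])
  if (!all(sheet$condition %in% c("control", "drought")))
    dn_input_error("condition must be 'control' or 'drought'")
  if (any(sheet$day < 0) || any(sheet$day != round(sheet$day)))
    dn_input_error("day must be a non-negative integer")
  if (any(sheet$replicate < 1))
    dn_input_error("replicate must be a positive integer")
  sheet$day <- as.integer(sheet$day)
  sheet$replicate <- as.integer(sheet$replicate)
  sheet
}

#' Read / write a sample sheet (TSV)
#'
#' @param path file path.
#' @return \code{read_sample_sheet}: a validated sample sheet data.frame.
#' @export
read_sample_sheet <- function(path) validate_sample_sheet(dn_read_tsv(path))

#' @rdname read_sample_sheet
#' @param sheet a validated sample sheet.
#' @export
write_sample_sheet <- function(sheet, path)
  dn_write_tsv(validate_sample_sheet(sheet), path)

#' Select the samples entering one variety-by-condition analysis
#'
#' Restricts a sample sheet to one variety and condition across all days and
#' replicates. With \code{include_day0 = TRUE} the shared day-0 baseline
#' samples (stored under condition \code{"control"}) are included regardless
#' of the requested condition, implementing the shared-baseline design.
#' The correlation stage uses the strict (condition-only) selection so that
#' the drought network reflects treated samples only; see the vignette.
#'
#' @param sheet sample sheet.
#' @param variety,condition labels to select.
#' @param include_day0 include shared day-0 samples in either condition.
#' @return The selected rows of \code{sheet}.
#' @export
samples_for <- function(sheet, variety, condition, include_day0 = FALSE) {
  keep <- sheet$variety == variety &
    (sheet$condition == condition | (include_day0 & sheet$day == 0L))
  sheet[keep, , drop = FALSE]
}

dn_read_matrix <- function(path, what = "gene") {
  df <- dn_read_tsv(path)
  if (ncol(df) < 2)
    dn_input_error("matrix file %s needs an id column plus >=1 sample", path)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    dn_input_error("duplicate %s ID in %s: %s", what, path,
                   ids[duplicated(ids)][1])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!vapply(df[-1], is.numeric, logical(1)))[1]
    dn_input_error("non-numeric values in %s, column '%s'", path,
                   names(df)[-1][bad])
  }
  rownames(m) <- ids
  m
}

#' Read an expression matrix (genes x samples, FPKM scale)
#'
#' TSV with gene IDs in the first column and sample IDs as the header. All
#' values must be finite and non-negative; sample IDs must be declared in the
#' sample sheet. Genes whose values are all zero are retained and reported in
#' the \code{"all_zero"} attribute.
#'
#' @param path TSV file.
#' @param sheet validated sample sheet the columns must belong to.
#' @return numeric matrix with an \code{"all_zero"} attribute (gene IDs).
#' @export
read_expression <- function(path, sheet) {
  m <- dn_read_matrix(path, "gene")
  validate_expression(m, sheet, what = path)
}

#' @rdname read_expression
#' @param m genes x samples numeric matrix.
#' @param what label used in error messages.
#' @export
validate_expression <- function(m, sheet = NULL, what = "expression matrix") {
  if (any(!is.finite(m)))
    dn_input_error("non-finite values in %s", what)
  if (any(m < 0)) {
    idx <- which(m < 0, arr.ind = TRUE)[1, ]
    dn_input_error("negative value in %s at gene '%s', sample '%s'",
                   what, rownames(m)[idx[1]], colnames(m)[idx[2]])
  }
  if (!is.null(sheet)) {
    unknown <- setdiff(colnames(m), sheet$sample_id)
    if (length(unknown))
      dn_input_error("samples absent from sample sheet: %s",
                     paste(unknown, collapse = ", "))
  }
  attr(m, "all_zero") <- rownames(m)[rowSums(m) == 0]
  m
}

#' @rdname read_expression
#' @export
write_expression <- function(m, path, digits = 15) {
  df <- data.frame(gene_id = rownames(m),
                   signif(m, digits), check.names = FALSE)
  dn_write_tsv(df, path)
}

#' Read a hormone table (hormones x samples, ng per g fresh weight)
#'
#' @inheritParams read_expression
#' @return numeric matrix of strictly positive values.
#' @export
read_hormones <- function(path, sheet) {
  m <- dn_read_matrix(path, "hormone")
  if (any(!is.finite(m)) || any(m <= 0))
    dn_input_error("hormone levels must be positive and finite: %s", path)
  if (!is.null(sheet)) {
    unknown <- setdiff(colnames(m), sheet$sample_id)
    if (length(unknown))
      dn_input_error("hormone samples absent from sample sheet: %s",
                     paste(unknown, collapse = ", "))
  }
  m
}

#' @rdname read_hormones
#' @param m hormones x samples matrix.
#' @export
write_hormones <- function(m, path, digits = 15) {
  df <- data.frame(hormone_id = rownames(m),
                   signif(m, digits), check.names = FALSE)
  dn_write_tsv(df, path)
}

#' Read a pathway-membership table
#'
#' Maps gene IDs to a hormone-signaling pathway and a protein family (e.g.
#' PP2C, ABF, SnRK2). Columns: \code{gene_id}, \code{pathway}, \code{family}.
#'
#' @param path TSV file.
#' @return data.frame with unique gene IDs.
#' @export
read_pathways <- function(path) {
  df <- dn_read_tsv(path)
  need <- c("gene_id", "pathway", "family")
  if (!all(need %in% names(df)))
    dn_input_error("pathway table needs columns: %s", paste(need, collapse = ", "))
  if (anyDuplicated(df$gene_id))
    dn_input_error("duplicate gene_id in pathway table: %s",
                   df$gene_id[duplicated(df$gene_id)][1])
  if (any(nzchar(df$pathway) & !nzchar(df$family)))
    dn_input_error("family must be set when pathway is set")
  df
}

#' @rdname read_pathways
#' @param df pathway table.
#' @export
write_pathways <- function(df, path) dn_write_tsv(df, path)

#' Read and resolve a cross-variety homolog map
#'
#' Columns: \code{gene_id_v1}, \code{gene_id_v2}, optional \code{similarity}
#' in [0, 1]. \code{resolve_homologs} reduces a many-to-many map to a
#' one-to-one map by greedily keeping the highest-similarity pair, breaking
#' ties lexicographically by partner ID.
#'
#' @param path TSV file.
#' @return data.frame (resolved maps carry attribute \code{"resolved"}).
#' @export
read_homologs <- function(path) {
  df <- dn_read_tsv(path)
  if (!all(c("gene_id_v1", "gene_id_v2") %in% names(df)))
    dn_input_error("homolog map needs columns gene_id_v1, gene_id_v2")
  if (is.null(df$similarity)) df$similarity <- 1
  if (any(df$similarity < 0 | df$similarity > 1, na.rm = TRUE))
    dn_input_error("similarity must lie in [0, 1]")
  df
}

#' @rdname read_homologs
#' @param map homolog map data.frame.
#' @export
resolve_homologs <- function(map) {
  if (is.null(map$similarity)) map$similarity <- 1
  ord <- order(-map$similarity, map$gene_id_v1, map$gene_id_v2)
  map <- map[ord, , drop = FALSE]
  used1 <- used2 <- character()
  keep <- logical(nrow(map))
  for (i in seq_len(nrow(map))) {
    if (!(map$gene_id_v1[i] %in% used1) && !(map$gene_id_v2[i] %in% used2)) {
      keep[i] <- TRUE
      used1 <- c(used1, map$gene_id_v1[i])
      used2 <- c(used2, map$gene_id_v2[i])
    }
  }
  out <- map[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "resolved") <- TRUE
  out
}

#' @rdname read_homologs
#' @export
write_homologs <- function(map, path) dn_write_tsv(map, path)

edge_columns <- c("node_a", "node_b", "pearson_r", "pearson_p",
                  "spearman_rho", "spearman_p", "sign")

#' Write a network in a Cytoscape-ingestible format
#'
#' \code{sif} writes `nodeA <type> nodeB` lines with interaction type
#' \code{pos}, \code{neg} or \code{mixed}; \code{tsv} writes the full edge
#' table; \code{graphml} writes nodes and edges with all edge attributes.
#'
#' @param net a \code{dn_network} or \code{dn_common} object.
#' @param path output file.
#' @param format one of \code{"tsv"}, \code{"sif"}, \code{"graphml"}.
#' @return \code{path}, invisibly.
#' @export
write_network <- function(net, path, format = c("tsv", "sif", "graphml")) {
  if (length(format) != 1 || !format %in% c("tsv", "sif", "graphml"))
    dn_usage_error("unknown network format: %s",
                   paste(format, collapse = ","))
  edges <- network_edge_table(net)
  nodes <- network_node_table(net)
  if (format == "tsv") {
    dn_write_tsv(edges, path, header_lines = dn_provenance())
  } else if (format == "sif") {
    type <- ifelse(edges$sign == "+", "pos",
                   ifelse(edges$sign == "-", "neg", "mixed"))
    writeLines(if (nrow(edges)) paste(edges$node_a, type, edges$node_b)
               else character(), path)
  } else {
    write_graphml(nodes, edges, path)
  }
  invisible(path)
}

network_edge_table <- function(net) {
  if (inherits(net, "dn_common")) {
    e <- net$edges
    data.frame(node_a = e$family_a, node_b = e$family_b, sign = e$sign,
               mean_coefficient = e$mean_coefficient,
               mean_pos = e$mean_pos, mean_neg = e$mean_neg,
               n_pos = e$n_pos, n_neg = e$n_neg,
               variety_labels = e$variety_labels,
               stringsAsFactors = FALSE)
  } else if (inherits(net, "dn_network")) {
    net$edges
  } else if (is.data.frame(net)) net
  else dn_usage_error("cannot write object of class %s as a network",
                      paste(class(net), collapse = "/"))
}

network_node_table <- function(net) {
  if (inherits(net, "dn_network") && !is.null(net$nodes)) return(net$nodes)
  e <- network_edge_table(net)
  data.frame(node = sort(unique(c(e$node_a, e$node_b))),
             stringsAsFactors = FALSE)
}

write_graphml <- function(nodes, edges, path) {
  doc <- xml2::xml_new_root(
    "graphml",
    xmlns = "http://graphml.graphdrawing.org/xmlns")
  attr_cols <- setdiff(names(edges), c("node_a", "node_b"))
  for (k in attr_cols) {
    key <- xml2::xml_add_child(doc, "key", id = k, `for` = "edge",
                               `attr.name` = k)
    xml2::xml_set_attr(key, "attr.type",
                       if (is.numeric(edges[[k]])) "double" else "string")
  }
  g <- xml2::xml_add_child(doc, "graph", id = "G", edgedefault = "undirected")
  for (n in nodes$node) xml2::xml_add_child(g, "node", id = n)
  if (nrow(edges)) for (i in seq_len(nrow(edges))) {
    e <- xml2::xml_add_child(g, "edge",
                             source = edges$node_a[i],
                             target = edges$node_b[i])
    for (k in attr_cols) {
      v <- edges[[k]][i]
      d <- xml2::xml_add_child(e, "data", key = k)
      xml2::xml_set_text(d, if (is.numeric(v)) format(v, digits = 12) else
        as.character(v))
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network_tsv <- function(path) dn_read_tsv(path)
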