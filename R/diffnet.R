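pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")

#' Classify edges as gained, lost or stable between conditions
#'
#' Compares the control and drought consensus networks of one variety by
#' canonical endpoint pair: \code{gained} edges are present under drought
#' only, \code{lost} under control only, \code{stable} in both (drought
#' coefficients are kept for stable edges).
#'
#' @param control_net,drought_net \code{dn_network} objects of the same
#'   variety.
#' @return a \code{dn_diffnet}: list with \code{variety}, \code{gained},
#'   \code{lost}, \code{stable} edge tables.
#' @export
differential_edges <- function(control_net, drought_net) {
  if (!identical(control_net$variety, drought_net$variety))
    dn_input_error("variety mismatch: '%s' vs '%s'",
                   control_net$variety, drought_net$variety)
  kc <- pair_key(control_net$edges$node_a, control_net$edges$node_b)
  kd <- pair_key(drought_net$edges$node_a, drought_net$edges$node_b)
  structure(list(
    variety = control_net$variety,
    gained = drought_net$edges[!(kd %in% kc), , drop = FALSE],
    lost   = control_net$edges[!(kc %in% kd), , drop = FALSE],
    stable = drought_net$edges[kd %in% kc, , drop = FALSE]),
    class = "dn_diffnet")
}

#' @export
print.dn_diffnet <- function(x, ...) {
  cat(sprintf("Differential network (%s): %d gained, %d lost, %d stable\n",
              x$variety, nrow(x$gained), nrow(x$lost), nrow(x$stable)))
  invisible(x)
}

node_families <- function(nodes, pathways) {
  fam <- pathways$family[match(nodes, pathways$gene_id)]
  # hormone nodes (absent from the pathway table) are their own family
  ifelse(is.na(fam) | !nzchar(fam), nodes, fam)
}

#' Collapse gene-level edges to protein-family-level edges
#'
#' Maps each gene endpoint to its protein family (hormone nodes stand for
#' themselves), groups edges by unordered family pair and sign, and
#' averages the Pearson coefficients per sign. A family pair observed with
#' both signs yields one \code{mixed} edge carrying both component means.
#' Gene endpoints lacking a family annotation are excluded with a warning.
#' Collapsing an already family-level edge set is the identity.
#'
#' @param edges edge table with columns node_a, node_b, pearson_r (a
#'   \code{mean_coefficient} column is used if pearson_r is absent).
#' @param pathways pathway table used for the gene-to-family map.
#' @return data.frame with family_a, family_b, sign, mean_pos, mean_neg,
#'   n_pos, n_neg, mean_coefficient (NA for mixed edges).
#' @export
collapse_to_family <- function(edges, pathways) {
  empty <- data.frame(family_a = character(), family_b = character(),
                      sign = character(), mean_pos = numeric(),
                      mean_neg = numeric(), n_pos = integer(),
                      n_neg = integer(), mean_coefficient = numeric(),
                      stringsAsFactors = FALSE)
  if (!nrow(edges)) return(empty)
  r <- if (!is.null(edges$pearson_r)) edges$pearson_r else
    edges$mean_coefficient
  # a node is excluded iff it is a known gene whose family is unset;
  # nodes absent from the table (hormones) stand for themselves
  unannotated <- pathways$gene_id[!nzchar(pathways$family)]
  bad_nodes <- intersect(unique(c(edges$node_a, edges$node_b)), unannotated)
  if (length(bad_nodes)) {
    warning(sprintf("excluding gene(s) without family annotation: %s",
                    paste(bad_nodes, collapse = ", ")))
    keep <- !(edges$node_a %in% bad_nodes | edges$node_b %in% bad_nodes)
    edges <- edges[keep, , drop = FALSE]; r <- r[keep]
    if (!nrow(edges)) return(empty)
  }
  fa <- node_families(edges$node_a, pathways)
  fb <- node_families(edges$node_b, pathways)
  # within-family gene-gene edges collapse to self-loops; drop them (the
  # family graph relates distinct protein types)
  keep <- fa != fb
  edges <- edges[keep, , drop = FALSE]; r <- r[keep]
  fa <- fa[keep]; fb <- fb[keep]
  if (!nrow(edges)) return(empty)
  family_a <- pmin(fa, fb); family_b <- pmax(fa, fb)
  key <- paste(family_a, family_b, sep = "\r")
  out <- lapply(split(seq_along(key), key), function(i) {
    rp <- r[i][r[i] >= 0]; rn <- r[i][r[i] < 0]
    sgn <- if (length(rp) && length(rn)) "mixed" else
      if (length(rp)) "+" else "-"
    data.frame(family_a = family_a[i[1]], family_b = family_b[i[1]],
               sign = sgn,
               mean_pos = if (length(rp)) mean(rp) else NA_real_,
               mean_neg = if (length(rn)) mean(rn) else NA_real_,
               n_pos = length(rp), n_neg = length(rn),
               mean_coefficient = if (sgn == "+") mean(rp) else
                 if (sgn == "-") mean(rn) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  out[order(out$family_a, out$family_b), , drop = FALSE]
}

#' Cross-variety common network at the protein-family level
#'
#' A family-pair edge qualifies if each variety's drought network contains
#' at least one gene-level consensus edge between those families (mode
#' \code{"drought-present"}, default); in mode \code{"drought-specific"}
#' the contributing edges must additionally be gained edges (absent from
#' that variety's control network), so the differential networks are
#' required. Contributing coefficients from both varieties are pooled:
#' \code{mean_pos}/\code{mean_neg} are the means of positive/negative
#' Pearson coefficients. A pair observed with both signs is \code{mixed};
#' the label of any variety contributing a sign the other lacks is recorded
#' in \code{variety_labels}.
#'
#' @param drought_v1,drought_v2 \code{dn_network} drought networks.
#' @param pathways_v1,pathways_v2 pathway tables per variety (may be the
#'   same object).
#' @param mode \code{"drought-present"} or \code{"drought-specific"}.
#' @param diff_v1,diff_v2 \code{dn_diffnet} objects, required for mode
#'   \code{"drought-specific"}.
#' @return a \code{dn_common}: list with \code{edges},
#'   \code{varieties}, \code{mode}.
#' @export
common_network <- function(drought_v1, drought_v2,
                           pathways_v1, pathways_v2 = pathways_v1,
                           mode = c("drought-present", "drought-specific"),
                           diff_v1 = NULL, diff_v2 = NULL) {
  mode <- match.arg(mode)
  e1 <- drought_v1$edges; e2 <- drought_v2$edges
  if (mode == "drought-specific") {
    if (is.null(diff_v1) || is.null(diff_v2))
      dn_usage_error("mode 'drought-specific' needs diff_v1 and diff_v2")
    e1 <- diff_v1$gained; e2 <- diff_v2$gained
  }
  f1 <- collapse_to_family(e1, pathways_v1)
  f2 <- collapse_to_family(e2, pathways_v2)
  k1 <- paste(f1$family_a, f1$family_b, sep = "\r")
  k2 <- paste(f2$family_a, f2$family_b, sep = "\r")
  shared <- intersect(k1, k2)
  v1 <- drought_v1$variety %||% "v1"
  v2 <- drought_v2$variety %||% "v2"
  edges <- lapply(shared, function(k) {
    a <- f1[k1 == k, ]; b <- f2[k2 == k, ]
    n_pos <- a$n_pos + b$n_pos; n_neg <- a$n_neg + b$n_neg
    wmean <- function(m1, n1, m2, n2) {
      tot <- n1 + n2
      if (tot == 0) NA_real_ else
        sum(c(m1 * n1, m2 * n2), na.rm = TRUE) / tot
    }
    mean_pos <- wmean(a$mean_pos, a$n_pos, b$mean_pos, b$n_pos)
    mean_neg <- wmean(a$mean_neg, a$n_neg, b$mean_neg, b$n_neg)
    sgn <- if (n_pos > 0 && n_neg > 0) "mixed" else
      if (n_pos > 0) "+" else "-"
    labels <- character()
    if (sgn == "mixed") {
      if (xor(a$n_pos > 0, b$n_pos > 0))
        labels <- c(labels, if (a$n_pos > 0) v1 else v2)
      if (xor(a$n_neg > 0, b$n_neg > 0))
        labels <- c(labels, if (a$n_neg > 0) v1 else v2)
    }
    data.frame(family_a = a$family_a, family_b = a$family_b, sign = sgn,
               mean_pos = mean_pos, mean_neg = mean_neg,
               n_pos = n_pos, n_neg = n_neg,
               mean_coefficient = if (sgn == "+") mean_pos else
                 if (sgn == "-") mean_neg else NA_real_,
               variety_labels = paste(unique(labels), collapse = ","),
               stringsAsFactors = FALSE)
  })
  edges <- if (length(edges))
    do.call(rbind, c(edges, list(make.row.names = FALSE))) else
      cbind(collapse_to_family(e1[0, , drop = FALSE], pathways_v1),
            variety_labels = character())
  edges <- edges[order(edges$family_a, edges$family_b), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(edges = edges, varieties = c(v1, v2), mode = mode),
            class = "dn_common")
}

#' @export
print.dn_common <- function(x, ...) {
  cat(sprintf("Common network (%s; %s): %d family-level edges\n",
              paste(x$varieties, collapse = " & "), x$mode, nrow(x$edges)))
  if (nrow(x$edges)) {
    show <- x$edges[, c("family_a", "sign", "family_b", "mean_pos",
                        "mean_neg", "variety_labels")]
    print(show, row.names = FALSE)
  }
  invisible(x)
}
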