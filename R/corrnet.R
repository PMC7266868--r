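#' Pearson correlation with a two-sided t-test p-value
#'
#' The p-value uses \eqn{t = r \sqrt{(n-2)/(1-r^2)}} against a Student t
#' distribution with n - 2 degrees of freedom; \eqn{|r| = 1} yields p = 0.
#' Zero variance in either vector gives \code{NA}s with a warning (the pair
#' is excluded upstream).
#'
#' @param x,y numeric vectors of equal length, n >= 3, finite values.
#' @return list with elements \code{r} and \code{p}.
#' @export
pearson_with_p <- function(x, y) {
  if (length(x) != length(y)) dn_input_error("x and y differ in length")
  n <- length(x)
  if (n < 3) dn_input_error("need n >= 3 observations, got %d", n)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    dn_input_error("non-finite values in correlation input")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance: correlation undefined, pair excluded")
    return(list(r = NA_real_, p = NA_real_))
  }
  r <- stats::cor(x, y)
  list(r = r, p = cor_p_from_r(r, n))
}

#' Spearman rank correlation with a t-approximation p-value
#'
#' rho is the Pearson correlation of mid-ranks (ties receive average ranks);
#' the p-value applies the same t-approximation as [pearson_with_p()] to rho,
#' for uniformity across methods at small n (approximate; documented).
#'
#' @inheritParams pearson_with_p
#' @return list with elements \code{rho} and \code{p}.
#' @export
spearman_with_p <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    warning("zero rank variance: correlation undefined, pair excluded")
    return(list(rho = NA_real_, p = NA_real_))
  }
  out <- pearson_with_p(rx, ry)
  list(rho = out$r, p = out$p)
}

cor_p_from_r <- function(r, n) {
  out <- r                     # keeps dim/dimnames for matrix input
  rv <- pmin(1, pmax(-1, as.vector(r)))
  tt <- rv * sqrt((n - 2) / pmax(1 - rv^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  p[abs(rv) >= 1] <- 0
  out[] <- p
  out
}

# All-pairs correlation across the columns of `m` (samples x nodes), both
# methods, vectorized. Returns matrices r, p_r, rho, p_rho.
cor_all_pairs <- function(m) {
  n <- nrow(m)
  r <- stats::cor(m)
  ranks <- apply(m, 2, rank, ties.method = "average")
  rho <- stats::cor(ranks)
  list(r = r, p_r = cor_p_from_r(r, n),
       rho = rho, p_rho = cor_p_from_r(rho, n))
}

#' Z-score scaling of log2-transformed rows
#'
#' Applies log2(x + 1) and then standardizes each row to mean 0, sd 1
#' (sample sd, n - 1 denominator). Constant rows map to all zeros. This is
#' the display transform used for expression-pattern heatmaps.
#'
#' @param m numeric matrix (genes x samples, FPKM scale).
#' @return matrix of the same shape.
#' @export
zscore_rows <- function(m) {
  lm2 <- log2(m + 1)
  mu <- rowMeans(lm2)
  sd <- apply(lm2, 1, stats::sd)
  out <- (lm2 - mu) / ifelse(sd == 0, 1, sd)
  out[sd == 0, ] <- 0
  out
}

#' Build the consensus correlation network for one variety and condition
#'
#' Nodes are the differentially expressed genes annotated to any hormone
#' signaling pathway, plus all hormones. Gene abundances are correlated on
#' the log2(FPKM + 1) scale, hormones on their native ng/g scale. Every
#' unordered node pair is evaluated by both Pearson and Spearman correlation;
#' an edge is retained iff |coefficient| > \code{r_threshold} and
#' p < \code{p_threshold} under BOTH methods (strict inequalities). Both
#' methods' statistics are kept for every pair in the \code{pairs} table
#' regardless of retention. No multiple-testing correction is applied to
#' edge p-values by default (fidelity choice); \code{bh_edges = TRUE} filters
#' on BH-adjusted p-values instead.
#'
#' @param expr genes x samples FPKM matrix.
#' @param hormones hormones x samples matrix (may be \code{NULL}).
#' @param pathways pathway table (\code{gene_id}, \code{pathway},
#'   \code{family}).
#' @param deg_genes character vector of DEG gene IDs (typically the union
#'   over treatment stages for this variety).
#' @param sheet sample sheet.
#' @param variety,condition which stratum to build.
#' @param r_threshold,p_threshold consensus thresholds (defaults 0.7, 0.05).
#' @param per_stage_means correlate per-day replicate means instead of
#'   replicate-level samples.
#' @param include_day0 include the shared day-0 baseline samples in the
#'   condition's sample set (default \code{FALSE}: strict condition match).
#' @param bh_edges apply Benjamini-Hochberg adjustment to each method's
#'   p-values across pairs before thresholding (default off).
#' @return A \code{dn_network}: list with \code{variety}, \code{condition},
#'   \code{nodes} (node, type, pathway, family), \code{edges} (consensus
#'   edges) and \code{pairs} (all evaluated pairs).
#' @export
build_network <- function(expr, hormones, pathways, deg_genes, sheet,
                          variety, condition,
                          r_threshold = 0.7, p_threshold = 0.05,
                          per_stage_means = FALSE, include_day0 = FALSE,
                          bh_edges = FALSE) {
  sel <- samples_for(sheet, variety, condition, include_day0 = include_day0)
  if (nrow(sel) == 0)
    dn_input_error("no samples for variety '%s', condition '%s'",
                   variety, condition)
  path_genes <- pathways$gene_id[nzchar(pathways$pathway)]
  genes <- intersect(intersect(deg_genes, path_genes), rownames(expr))
  gmat <- log2(expr[genes, sel$sample_id, drop = FALSE] + 1)
  hmat <- if (!is.null(hormones))
    hormones[, sel$sample_id, drop = FALSE] else NULL
  m <- t(rbind(gmat, hmat))          # samples x nodes
  if (per_stage_means) {
    day <- sel$day[match(rownames(m), sel$sample_id)]
    m <- apply(m, 2, function(v) tapply(v, day, mean))
    if (is.null(dim(m))) m <- matrix(m, nrow = 1)
  }
  if (nrow(m) < 3)
    dn_input_error("fewer than 3 usable samples (%d) for %s/%s",
                   nrow(m), variety, condition)
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    warning(sprintf("dropping constant node(s): %s",
                    paste(colnames(m)[sds == 0], collapse = ", ")))
    m <- m[, sds > 0, drop = FALSE]
  }
  node_ids <- colnames(m)
  nodes <- data.frame(
    node = node_ids,
    type = ifelse(node_ids %in% rownames(expr), "gene", "hormone"),
    pathway = pathways$pathway[match(node_ids, pathways$gene_id)],
    family = pathways$family[match(node_ids, pathways$gene_id)],
    stringsAsFactors = FALSE)

  p <- ncol(m)
  if (p >= 2) {
    cc <- cor_all_pairs(m)
    idx <- which(upper.tri(cc$r), arr.ind = TRUE)
    a <- node_ids[idx[, 1]]; b <- node_ids[idx[, 2]]
    swap <- a > b
    pairs <- data.frame(
      node_a = ifelse(swap, b, a), node_b = ifelse(swap, a, b),
      pearson_r = cc$r[idx], pearson_p = cc$p_r[idx],
      spearman_rho = cc$rho[idx], spearman_p = cc$p_rho[idx],
      stringsAsFactors = FALSE)
    pairs$sign <- ifelse(pairs$pearson_r >= 0, "+", "-")
    pr <- pairs$pearson_p; sp <- pairs$spearman_p
    if (bh_edges) { pr <- bh_adjust(pr); sp <- bh_adjust(sp) }
    pairs$passes <- abs(pairs$pearson_r) > r_threshold & pr < p_threshold &
      abs(pairs$spearman_rho) > r_threshold & sp < p_threshold
    pairs <- pairs[order(pairs$node_a, pairs$node_b), , drop = FALSE]
    rownames(pairs) <- NULL
  } else {
    pairs <- data.frame(node_a = character(), node_b = character(),
                        pearson_r = numeric(), pearson_p = numeric(),
                        spearman_rho = numeric(), spearman_p = numeric(),
                        sign = character(), passes = logical(),
                        stringsAsFactors = FALSE)
  }
  edges <- pairs[pairs$passes, setdiff(names(pairs), "passes"), drop = FALSE]
  rownames(edges) <- NULL
  structure(list(variety = variety, condition = condition,
                 n_samples = nrow(m), nodes = nodes,
                 edges = edges, pairs = pairs),
            class = "dn_network")
}

#' @export
print.dn_network <- function(x, ...) {
  cat(sprintf("Consensus correlation network: %s / %s\n",
              x$variety, x$condition))
  cat(sprintf("  %d nodes (%d genes, %d hormones), %d samples\n",
              nrow(x$nodes), sum(x$nodes$type == "gene"),
              sum(x$nodes$type == "hormone"), x$n_samples))
  cat(sprintf("  %d consensus edges of %d evaluated pairs\n",
              nrow(x$edges), nrow(x$pairs)))
  invisible(x)
}
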