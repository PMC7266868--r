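#' log2 fold change between group means on the FPKM scale
#'
#' \code{log2((mean(treat) + pseudocount) / (mean(control) + pseudocount))}.
#' The pseudocount (default 1, matching the log2(FPKM + 1) display
#' transform) stabilizes ratios near zero.
#'
#' @param treat_values,control_values numeric vectors, each non-empty.
#' @param pseudocount positive real added to both means.
#' @return a single log2 fold change.
#' @export
log2fc <- function(treat_values, control_values, pseudocount = 1) {
  if (!length(treat_values) || !length(control_values))
    dn_input_error("log2fc: both groups need at least one value")
  if (pseudocount < 0) dn_input_error("pseudocount must be non-negative")
  log2((mean(treat_values) + pseudocount) /
         (mean(control_values) + pseudocount))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Returns BH-adjusted values in input order. Values outside [0, 1] are an
#' input error.
#'
#' @param p numeric vector of p-values.
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    dn_input_error("p-values must lie in [0, 1]")
  m <- length(p)
  if (m <= 1) return(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(p[o] * m / (m:1)))[ro]
}

# Vectorized Welch two-sample t-test over matrix rows (x: genes x n1,
# y: genes x n2). Zero variance in both groups -> p = 1 when means equal,
# else p = 0 (degenerate separation).
row_welch <- function(x, y) {
  n1 <- ncol(x); n2 <- ncol(y)
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- rowSums((x - m1)^2) / (n1 - 1)
  v2 <- rowSums((y - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  df <- se2^2 / (v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1)))
  tt <- (m1 - m2) / sqrt(se2)
  p <- 2 * stats::pt(-abs(tt), df = df)
  zero <- se2 == 0
  p[zero] <- ifelse(m1[zero] == m2[zero], 1, 0)
  p[zero & m1 == m2] <- 1
  list(t = tt, df = df, p = p)
}

#' Stage-wise DEG test (drought vs control at one time point)
#'
#' Per gene: Welch's two-sample t-test on log2(FPKM + 1) values, drought vs
#' control replicates at the given variety and day; BH adjustment across all
#' genes of the stage; a gene is a DEG iff |log2fc| >= log2(fc_threshold)
#' AND fdr < fdr_threshold. Day 0 is the shared baseline and is never
#' tested.
#'
#' @param expr genes x samples FPKM matrix.
#' @param sheet sample sheet.
#' @param variety,day stage to test (day > 0).
#' @param fc_threshold fold-change threshold on the FPKM scale (default 2).
#' @param fdr_threshold BH-adjusted significance threshold (default 0.01).
#' @param pseudocount passed to [log2fc()].
#' @return data.frame with columns gene_id, variety, day, log2fc, p_raw,
#'   fdr, is_deg.
#' @export
test_stage <- function(expr, sheet, variety, day,
                       fc_threshold = 2, fdr_threshold = 0.01,
                       pseudocount = 1) {
  if (day == 0)
    dn_input_error("day 0 is the shared baseline and is never tested")
  trt <- sheet$sample_id[sheet$variety == variety &
                           sheet$condition == "drought" & sheet$day == day]
  ctl <- sheet$sample_id[sheet$variety == variety &
                           sheet$condition == "control" & sheet$day == day]
  if (length(trt) < 2 || length(ctl) < 2)
    dn_input_error("need >=2 replicates per group at %s day %d (%d vs %d)",
                   variety, day, length(trt), length(ctl))
  xt <- expr[, trt, drop = FALSE]; xc <- expr[, ctl, drop = FALSE]
  lt <- log2(xt + 1); lc <- log2(xc + 1)
  w <- row_welch(lt, lc)
  lfc <- log2((rowMeans(xt) + pseudocount) / (rowMeans(xc) + pseudocount))
  # untestable genes: zero variance in both groups
  v0 <- apply(lt, 1, stats::sd) == 0 & apply(lc, 1, stats::sd) == 0
  p <- w$p
  p[v0] <- 1
  fdr <- bh_adjust(p)
  data.frame(gene_id = rownames(expr), variety = variety, day = day,
             log2fc = lfc, p_raw = p, fdr = fdr,
             is_deg = !v0 & abs(lfc) >= log2(fc_threshold) &
               fdr < fdr_threshold,
             stringsAsFactors = FALSE)
}

#' Call DEGs across all treatment stages of one variety
#'
#' Runs [test_stage()] for every day > 0 present in the sheet; stages whose
#' replication is insufficient are skipped with a warning.
#'
#' @inheritParams test_stage
#' @param days days to test; default all days > 0 in the sheet.
#' @return data.frame of stacked per-stage results.
#' @export
call_degs <- function(expr, sheet, variety, days = NULL,
                      fc_threshold = 2, fdr_threshold = 0.01,
                      pseudocount = 1) {
  if (is.null(days))
    days <- sort(unique(sheet$day[sheet$variety == variety & sheet$day > 0]))
  out <- list()
  for (d in days) {
    res <- tryCatch(
      test_stage(expr, sheet, variety, d, fc_threshold, fdr_threshold,
                 pseudocount),
      dn_input_error = function(e) {
        warning(sprintf("stage day %d skipped: %s", d, conditionMessage(e)))
        NULL
      })
    if (!is.null(res)) out[[as.character(d)]] <- res
  }
  if (!length(out)) return(NULL)
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' DEG gene sets per stage from a stacked DEG table
#'
#' @param deg_table output of [call_degs()].
#' @return named list of character vectors, one per day.
#' @export
deg_sets <- function(deg_table) {
  lapply(split(deg_table, deg_table$day),
         function(d) d$gene_id[d$is_deg])
}

#' Union of DEGs over all stages
#'
#' @inheritParams deg_sets
#' @return character vector of gene IDs.
#' @export
deg_union <- function(deg_table)
  sort(unique(deg_table$gene_id[deg_table$is_deg]))

#' Venn-region and adjacent-stage overlap accounting of DEG sets
#'
#' Computes all 2^k - 1 Venn region counts across k stage DEG sets plus the
#' shared-DEG counts between adjacent stages.
#'
#' @param sets named list (>= 2 elements) of per-stage DEG gene-ID vectors,
#'   in stage order.
#' @return list with \code{venn} (named region counts, names like
#'   \code{"d2&d5"}), \code{adjacent} (shared counts between consecutive
#'   stages), \code{per_stage} sizes, and \code{union_size}.
#' @export
stage_overlaps <- function(sets) {
  if (length(sets) < 2) dn_input_error("need >= 2 stages")
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    names(sets) <- paste0("S", seq_along(sets))
  k <- length(sets)
  genes <- unique(unlist(sets))
  member <- vapply(sets, function(s) genes %in% s, logical(length(genes)))
  if (length(genes) == 1) member <- matrix(member, nrow = 1)
  pattern <- apply(member, 1, function(row)
    paste(names(sets)[row], collapse = "&"))
  # every non-empty subset, in binary-counting order
  region_names <- unlist(lapply(seq_len(2^k - 1), function(bits) {
    sel <- as.logical(bitwAnd(bits, 2^(seq_len(k) - 1)))
    paste(names(sets)[sel], collapse = "&")
  }))
  venn <- stats::setNames(integer(length(region_names)), region_names)
  tab <- table(pattern)
  venn[names(tab)] <- as.integer(tab)
  adj <- if (k >= 2) vapply(seq_len(k - 1), function(i)
    length(intersect(sets[[i]], sets[[i + 1]])), integer(1)) else integer()
  names(adj) <- if (k >= 2)
    paste(names(sets)[-k], names(sets)[-1], sep = "&") else character()
  list(venn = venn, adjacent = adj,
       per_stage = vapply(sets, length, integer(1)),
       union_size = length(genes))
}

#' Cross-variety common DEGs at one stage
#'
#' Pairs (g1, g2) such that g1 is a DEG in variety 1 at the given day, g2 is
#' its homolog under the resolved one-to-one map, and g2 is a DEG in variety
#' 2 at the same day. DEGs without a mapped homolog are excluded and
#' reported via message.
#'
#' @param deg_v1,deg_v2 stacked DEG tables (one per variety).
#' @param map homolog map; resolved with [resolve_homologs()] if needed.
#' @param day stage to compare.
#' @return data.frame with columns gene_id_v1, gene_id_v2.
#' @export
cross_variety_common <- function(deg_v1, deg_v2, map, day) {
  if (!isTRUE(attr(map, "resolved"))) map <- resolve_homologs(map)
  s1 <- deg_v1$gene_id[deg_v1$is_deg & deg_v1$day == day]
  s2 <- deg_v2$gene_id[deg_v2$is_deg & deg_v2$day == day]
  unmapped <- setdiff(s1, map$gene_id_v1)
  if (length(unmapped))
    message(sprintf("day %d: %d DEG(s) in variety 1 lack a homolog and are excluded",
                    day, length(unmapped)))
  hit <- map[map$gene_id_v1 %in% s1 & map$gene_id_v2 %in% s2,
             c("gene_id_v1", "gene_id_v2"), drop = FALSE]
  rownames(hit) <- NULL
  hit
}
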