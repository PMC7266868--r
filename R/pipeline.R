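#' Run the full analysis pipeline on one dataset
#'
#' Per variety: stage-wise DEG calling, control and drought consensus
#' networks over (union-of-stage DEG pathway genes + hormones), and the
#' differential edge classification; then the cross-variety family-level
#' common network and its degree/hub report.
#'
#' @param expr genes x samples FPKM matrix (shared gene universe).
#' @param sheet sample sheet covering the matrix columns.
#' @param hormones hormones x samples matrix (or \code{NULL}).
#' @param pathways pathway table.
#' @param homologs homolog map (used for cross-variety common DEG counts).
#' @param fc_threshold,fdr_threshold DEG thresholds (defaults 2, 0.01).
#' @param r_threshold,p_threshold consensus edge thresholds (0.7, 0.05).
#' @param mode common-network mode, see [common_network()].
#' @param per_stage_means correlate per-day means instead of replicates.
#' @return list with \code{deg} (per variety), \code{overlaps} (per
#'   variety), \code{common_degs} (per day), \code{networks} (per variety,
#'   control and drought), \code{diff} (per variety), \code{common},
#'   \code{hub_report}, \code{hub_summary}.
#' @export
run_pipeline <- function(expr, sheet, hormones, pathways, homologs = NULL,
                         fc_threshold = 2, fdr_threshold = 0.01,
                         r_threshold = 0.7, p_threshold = 0.05,
                         mode = "drought-present",
                         per_stage_means = FALSE) {
  varieties <- unique(sheet$variety)
  deg <- networks <- diff <- overlaps <- list()
  for (v in varieties) {
    deg[[v]] <- call_degs(expr, sheet, v, fc_threshold = fc_threshold,
                          fdr_threshold = fdr_threshold)
    sets <- deg_sets(deg[[v]])
    names(sets) <- paste0("d", names(sets))
    overlaps[[v]] <- if (length(sets) >= 2) stage_overlaps(sets) else NULL
    dg <- deg_union(deg[[v]])
    networks[[v]] <- list(
      control = build_network(expr, hormones, pathways, dg, sheet, v,
                              "control", r_threshold, p_threshold,
                              per_stage_means = per_stage_means),
      drought = build_network(expr, hormones, pathways, dg, sheet, v,
                              "drought", r_threshold, p_threshold,
                              per_stage_means = per_stage_means))
    diff[[v]] <- differential_edges(networks[[v]]$control,
                                    networks[[v]]$drought)
  }
  common <- common_degs <- NULL
  hub_report <- hub_sum <- NULL
  if (length(varieties) >= 2) {
    v1 <- varieties[1]; v2 <- varieties[2]
    common <- common_network(networks[[v1]]$drought, networks[[v2]]$drought,
                             pathways, pathways, mode = mode,
                             diff_v1 = diff[[v1]], diff_v2 = diff[[v2]])
    hub_report <- degree_centrality(common)
    hub_sum <- hub_summary(hub_report, common, pathways)
    if (!is.null(homologs)) {
      days <- sort(unique(deg[[v1]]$day))
      common_degs <- lapply(days, function(d)
        cross_variety_common(deg[[v1]], deg[[v2]], homologs, d))
      names(common_degs) <- paste0("d", days)
    }
  }
  list(deg = deg, overlaps = overlaps, common_degs = common_degs,
       networks = networks, diff = diff, common = common,
       hub_report = hub_report, hub_summary = hub_sum)
}
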