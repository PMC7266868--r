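#' Simulation configuration
#'
#' Describes the emulated study design: two varieties, control and drought
#' conditions, five sampling days (0, 2, 5, 15, 30) and three replicates,
#' with planted >= 2-fold DEGs and a planted hub-centred correlation module
#' that is active under drought only.
#'
#' Defaults encode the emulated design, with variance chosen for
#' testability (see the methods vignette): \code{dispersion} is the
#' replicate-level sd of log2(FPKM + 1); each emulated replicate pools
#' several plants, and 0.15 (roughly 11\% CV) keeps an 8-fold effect
#' reliably detectable by a Welch test at n = 3 (whose df can drop to 2).
#' \code{deg_log2fc} defaults to 3 (8-fold).
#'
#' @param varieties character vector of variety labels.
#' @param conditions condition labels (fixed: control, drought).
#' @param days sampling days, strictly increasing, starting at 0.
#' @param n_replicates replicates per variety x condition x day (>= 2).
#' @param n_genes total genes simulated.
#' @param n_pathway_genes genes annotated to hormone-signaling pathways
#'   (the first \code{n_pathway_genes} gene IDs).
#' @param deg_fraction fraction of genes planted as DEGs (in addition to the
#'   hub module genes, which are always DEGs).
#' @param deg_log2fc planted log2 fold change (>= 1 so planted DEGs pass the
#'   2-fold rule in expectation).
#' @param dispersion sd of log2(FPKM + 1) across replicates.
#' @param hub_gene label of the planted hub gene.
#' @param hub_partners named character vector: names are partner gene
#'   labels, values their edge signs ("+" or "-"); all distinct from
#'   \code{hub_gene}.
#' @param planted_r target |population correlation| of hub-module pairs
#'   under drought, in (0.7, 1].
#' @param couple_aba also couple the ABA hormone to the hub's latent factor
#'   (positive sign).
#' @param aba_effect,iaa_effect drought/control hormone ratios at the peak
#'   stages (defaults 3 and 2.5).
#' @param seed integer seed; all stochastic operations derive their RNG
#'   streams from it.
#' @return a validated \code{dn_sim_config} list.
#' @export
sim_config <- function(varieties = c("K326", "BX"),
                       conditions = c("control", "drought"),
                       days = c(0L, 2L, 5L, 15L, 30L),
                       n_replicates = 3L,
                       n_genes = 200L,
                       n_pathway_genes = 30L,
                       deg_fraction = 0.1,
                       deg_log2fc = 3,
                       dispersion = 0.15,
                       hub_gene = "G0001",
                       hub_partners = c(G0002 = "+", G0003 = "+",
                                        G0004 = "+", G0005 = "-",
                                        G0006 = "-", G0007 = "+",
                                        G0008 = "-", G0009 = "+"),
                       planted_r = 0.95,
                       couple_aba = FALSE,
                       aba_effect = 3,
                       iaa_effect = 2.5,
                       seed = 20200527) {
  cfg <- list(varieties = varieties, conditions = conditions,
              days = as.integer(days), n_replicates = as.integer(n_replicates),
              n_genes = as.integer(n_genes),
              n_pathway_genes = as.integer(n_pathway_genes),
              deg_fraction = deg_fraction, deg_log2fc = deg_log2fc,
              dispersion = dispersion, hub_gene = hub_gene,
              hub_partners = hub_partners, planted_r = planted_r,
              couple_aba = couple_aba, aba_effect = aba_effect,
              iaa_effect = iaa_effect, seed = as.integer(seed))
  validate_sim_config(cfg)
}

#' @rdname sim_config
#' @param cfg a config list to validate.
#' @export
validate_sim_config <- function(cfg) {
  d <- cfg$days
  if (length(d) < 1 || d[1] != 0 || (length(d) > 1 && any(diff(d) <= 0)))
    dn_config_error("days must be strictly increasing and start at 0")
  if (cfg$n_replicates < 2 && length(d) > 1)
    dn_config_error("n_replicates must be >= 2")
  if (cfg$n_replicates < 1) dn_config_error("n_replicates must be >= 1")
  if (cfg$deg_log2fc < 1)
    dn_config_error("deg_log2fc must be >= 1 (2-fold rule)")
  if (abs(cfg$planted_r) <= 0.7 || abs(cfg$planted_r) > 1)
    dn_config_error("|planted_r| must lie in (0.7, 1]")
  if (length(cfg$hub_partners)) {
    if (cfg$hub_gene %in% names(cfg$hub_partners))
      dn_config_error("hub_partners must be distinct from hub_gene")
    if (!all(cfg$hub_partners %in% c("+", "-")))
      dn_config_error("hub_partners signs must be '+' or '-'")
  }
  if (cfg$deg_fraction < 0 || cfg$deg_fraction > 1)
    dn_config_error("deg_fraction must lie in [0, 1]")
  if (cfg$dispersion < 0) dn_config_error("dispersion must be positive")
  structure(cfg, class = "dn_sim_config")
}

#' Generate the sample design from a simulation config
#'
#' One row per variety x condition x day x replicate, with day-0 samples
#' listed once per variety and replicate (shared pre-treatment baseline,
#' stored under condition \code{"control"}). Sample IDs follow a
#' \code{<variety>_<C|D>_d<day>_r<rep>} scheme.
#'
#' @param cfg a [sim_config()].
#' @return a validated sample sheet.
#' @export
generate_design <- function(cfg) {
  cfg <- validate_sim_config(cfg)
  rows <- list()
  for (v in cfg$varieties) {
    for (d in cfg$days) {
      conds <- if (d == 0) "control" else cfg$conditions
      for (cond in conds) {
        for (r in seq_len(cfg$n_replicates)) {
          rows[[length(rows) + 1]] <- data.frame(
            sample_id = sprintf("%s_%s_d%d_r%d", v,
                                if (cond == "control") "C" else "D", d, r),
            variety = v, condition = cond, day = d, replicate = r,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  validate_sample_sheet(do.call(rbind, rows))
}

# Shared time-course factor: the deterministic drought-stress trajectory
# module genes ride under treatment; nonzero only for drought samples at
# days > 0. One value per day (replicates at the same day share it, so
# within-day replicate variance stays at `dispersion` and DEG power is
# unaffected): a centred log(day) ramp, i.e. a progressively deepening
# stress response, scaled to exact variance tau^2 over the treatment
# days. tau is calibrated so that the population correlation between two
# module members across the drought samples equals planted_r: each member
# loads the trajectory with coefficient 1 on top of iid replicate noise
# with sd = dispersion, giving r = tau^2 / (tau^2 + dispersion^2).
# Making the trajectory deterministic (rather than day-level random
# effects) keeps that calibration exact in every run; the stochastic part
# of the model is the replicate noise.
latent_factor <- function(cfg, design) {
  r <- min(cfg$planted_r, 1 - 1e-12)
  tau <- min(cfg$dispersion * sqrt(r / (1 - r)), 1e6)
  days_t <- cfg$days[cfg$days > 0]
  u <- if (length(days_t) > 1) {
    x <- log(days_t)
    (x - mean(x)) / sqrt(mean((x - mean(x))^2))
  } else 0
  cells <- expand.grid(variety = cfg$varieties, day = days_t,
                       stringsAsFactors = FALSE)
  zeta <- tau * u[match(cells$day, days_t)]
  names(zeta) <- paste(cells$variety, cells$day)
  z <- stats::setNames(numeric(nrow(design)), design$sample_id)
  on_trt <- design$condition == "drought" & design$day > 0
  z[on_trt] <- zeta[paste(design$variety, design$day)[on_trt]]
  attr(z, "zeta") <- zeta
  z
}

#' Simulate an expression matrix with planted structure
#'
#' Gene abundances are log-normal on the log2(FPKM + 1) scale: baseline
#' log2 abundance per gene, iid Gaussian replicate noise with sd
#' \code{dispersion}. Planted DEGs (a random \code{deg_fraction} of genes
#' plus the hub module) get a signed \code{deg_log2fc} shift in all drought
#' samples at days > 0. Hub-module genes additionally load a shared latent
#' per-sample factor under drought (sign given by the partner's edge sign),
#' calibrated so every module pair has population |correlation|
#' \code{planted_r} under drought and 0 under control.
#'
#' @param cfg a [sim_config()].
#' @param design output of [generate_design()] for the same config.
#' @return list with \code{expr} (genes x samples FPKM matrix) and
#'   \code{truth} (planted DEGs per stage, planted edges, hub, and the gene
#'   metadata needed for recovery scoring).
#' @export
simulate_expression <- function(cfg, design) {
  cfg <- validate_sim_config(cfg)
  genes <- sprintf("G%04d", seq_len(cfg$n_genes))
  module <- if (length(cfg$hub_partners))
    c(cfg$hub_gene, names(cfg$hub_partners)) else character()
  if (length(module) && !all(module %in% genes))
    dn_config_error("hub_gene and hub_partners must be among the gene IDs")
  sgn <- if (length(module))
    stats::setNames(c(1, ifelse(cfg$hub_partners == "+", 1, -1)), module)
  else stats::setNames(numeric(), character())

  n_deg <- round(cfg$deg_fraction * cfg$n_genes)
  out <- with_seed(cfg$seed, {
    mu <- stats::runif(cfg$n_genes, 2, 8)
    # module genes are well-expressed signaling genes; keeping their
    # baseline high ensures the planted down-swings never clip at the
    # FPKM floor (clipping would flatten the planted correlation)
    mu[match(module, genes)] <- stats::runif(length(module), 6.5, 9)
    extra <- sample(setdiff(genes, module), min(n_deg, cfg$n_genes -
                                                  length(module)))
    deg_sign <- stats::setNames(sample(c(-1, 1), length(extra), TRUE), extra)
    noise <- matrix(stats::rnorm(cfg$n_genes * nrow(design), 0,
                                 cfg$dispersion),
                    nrow = cfg$n_genes)
    list(mu = mu, extra = extra, deg_sign = deg_sign, noise = noise)
  })
  mu <- stats::setNames(out$mu, genes)
  deg_sign <- c(out$deg_sign, sgn)            # module genes are DEGs too
  planted <- names(deg_sign)

  lmat <- matrix(mu, nrow = cfg$n_genes, ncol = nrow(design)) + out$noise
  dimnames(lmat) <- list(genes, design$sample_id)
  on_trt <- design$condition == "drought" & design$day > 0
  lmat[planted, on_trt] <- lmat[planted, on_trt] +
    deg_sign[planted] * cfg$deg_log2fc
  z <- latent_factor(cfg, design)
  lmat[module, ] <- lmat[module, ] + outer(sgn[module], z)
  expr <- pmax(2^lmat - 1, 0)

  # per-variety, per-stage planted DEG truth: module genes ride the latent
  # trajectory, so their realized expected log2FC at stage d is
  # sign * (deg_log2fc + zeta[v, d]); a gene is a planted DEG at a stage
  # only if that expected effect passes the 2-fold rule (|lfc| >= 1).
  zeta <- attr(z, "zeta")
  stage_deg <- lapply(stats::setNames(nm = cfg$varieties), function(v) {
    out <- lapply(cfg$days[cfg$days > 0], function(d) {
      lfc <- deg_sign[planted] * cfg$deg_log2fc
      in_mod <- planted %in% module
      lfc[in_mod] <- deg_sign[planted][in_mod] *
        (cfg$deg_log2fc + zeta[paste(v, d)])
      df <- data.frame(gene_id = planted, log2fc = unname(lfc),
                       stringsAsFactors = FALSE)
      df[abs(df$log2fc) >= 1, , drop = FALSE]
    })
    names(out) <- paste0("d", cfg$days[cfg$days > 0])
    out
  })
  partners <- names(cfg$hub_partners)
  edges <- data.frame(
    node_a = pmin(cfg$hub_gene, partners),
    node_b = pmax(cfg$hub_gene, partners),
    sign = unname(cfg$hub_partners), stringsAsFactors = FALSE)
  truth <- list(deg_genes = stage_deg, planted_edges = edges,
                hub = cfg$hub_gene, module = module,
                deg_sign = deg_sign, factor = zeta, genes = genes)
  list(expr = expr, truth = truth)
}

#' Pathway-membership table for the simulated genes
#'
#' The hub gene is annotated as family PP2C in the abscisic acid pathway;
#' partners receive distinct families across hormone pathways; remaining
#' pathway genes cycle through a family pool; genes beyond
#' \code{n_pathway_genes} are unannotated.
#'
#' @param cfg a [sim_config()].
#' @return pathway table data.frame.
#' @export
simulate_pathways <- function(cfg) {
  cfg <- validate_sim_config(cfg)
  genes <- sprintf("G%04d", seq_len(cfg$n_genes))
  # "AUX/IAA" (auxin-responsive protein family) is deliberately distinct
  # from the hormone node label "IAA"
  fam_pool <- data.frame(
    family = c("ABF", "SnRK2", "GID", "A-ARR", "BZR", "AUX/IAA", "SAUR",
               "AUX1", "PYR", "JAZ"),
    pathway = c("abscisic acid", "abscisic acid", "gibberellin", "cytokinin",
                "brassinosteroid", "auxin", "auxin", "auxin",
                "abscisic acid", "jasmonic acid"),
    stringsAsFactors = FALSE)
  df <- data.frame(gene_id = genes, pathway = "", family = "",
                   stringsAsFactors = FALSE)
  npw <- min(cfg$n_pathway_genes, cfg$n_genes)
  idx <- rep(seq_len(nrow(fam_pool)), length.out = npw)
  df$pathway[seq_len(npw)] <- fam_pool$pathway[idx]
  df$family[seq_len(npw)] <- fam_pool$family[idx]
  hub_i <- match(cfg$hub_gene, genes)
  df$pathway[hub_i] <- "abscisic acid"; df$family[hub_i] <- "PP2C"
  partners <- names(cfg$hub_partners)
  pi <- match(partners, genes)
  fam_i <- rep(seq_len(nrow(fam_pool)), length.out = length(partners))
  df$pathway[pi] <- fam_pool$pathway[fam_i]
  df$family[pi] <- fam_pool$family[fam_i]
  df
}

#' Identity homolog map for the shared simulated gene universe
#'
#' The simulator uses one gene universe for both varieties, so the homolog
#' map is the identity with similarity 1.
#'
#' @param cfg a [sim_config()].
#' @return resolved homolog map.
#' @export
simulate_homologs <- function(cfg) {
  genes <- sprintf("G%04d", seq_len(cfg$n_genes))
  resolve_homologs(data.frame(gene_id_v1 = genes, gene_id_v2 = genes,
                              similarity = 1, stringsAsFactors = FALSE))
}

hormone_baselines <- c(ZR = 8, IAA = 45, GA3 = 18, ABA = 60, BR = 4,
                       `JA-me` = 25)

# log2 drought/control ratio profile per hormone per day. ABA and IAA
# accumulate progressively under drought: their log2 effects are affine in
# the same centred log(day) coordinate the latent trajectory uses (slope
# 0.55 log2 units), anchored so that the ABA ratio at day 2 and the IAA
# ratio at day 5 equal the configured effect ratios exactly (the noiseless
# limits asserted by the tests). The other four hormones are flat. An
# effect ratio <= 1 disables that hormone's drought response entirely, so
# aba_effect = iaa_effect = 1 is the fully null world.
hormone_effect_profile <- function(cfg, day) {
  days_t <- cfg$days[cfg$days > 0]
  u <- if (length(days_t) > 1) {
    x <- log(days_t)
    (x - mean(x)) / sqrt(mean((x - mean(x))^2))
  } else rep(0, length(days_t))
  ud <- u[match(day, days_t)]
  slope <- 0.55
  anchor <- function(effect, anchor_day) {
    if (effect <= 1 || is.na(ud)) return(0)
    ua <- if (anchor_day %in% days_t) u[match(anchor_day, days_t)] else u[1]
    log2(effect) + slope * (ud - ua)
  }
  c(ZR = 0,
    IAA = anchor(cfg$iaa_effect, 5),
    GA3 = 0,
    ABA = anchor(cfg$aba_effect, 2),
    BR = 0,
    `JA-me` = 0)
}

#' Simulate hormone levels (ng per g fresh weight)
#'
#' Six hormones (ZR, IAA, GA3, ABA, BR, JA-me), log-normal noise around
#' condition- and day-specific expected levels: ABA is elevated under
#' drought at mid stages (days 2-15), IAA at later stages (days 5-30).
#' With \code{cfg$couple_aba = TRUE}, ABA additionally loads the hub
#' module's latent factor (positive sign), planting an ABA-hub correlation.
#'
#' @inheritParams simulate_expression
#' @return list with \code{hormones} (hormones x samples matrix) and
#'   \code{profiles} (expected level per hormone x condition x day).
#' @export
simulate_hormones <- function(cfg, design) {
  cfg <- validate_sim_config(cfg)
  H <- names(hormone_baselines)
  base <- log2(hormone_baselines)
  lmat <- matrix(base, nrow = length(H), ncol = nrow(design))
  dimnames(lmat) <- list(H, design$sample_id)
  for (j in seq_len(nrow(design))) {
    if (design$condition[j] == "drought" && design$day[j] > 0)
      lmat[, j] <- lmat[, j] + hormone_effect_profile(cfg, design$day[j])
  }
  noise <- with_seed(cfg$seed + 104729L,
                     matrix(stats::rnorm(length(lmat), 0, cfg$dispersion),
                            nrow = length(H)))
  lm2 <- lmat + noise
  if (isTRUE(cfg$couple_aba)) {
    z <- latent_factor(cfg, design)
    lm2["ABA", ] <- lm2["ABA", ] + z
  }
  hormones <- 2^lm2
  days <- cfg$days
  profiles <- expand.grid(hormone = H, condition = cfg$conditions,
                          day = days, stringsAsFactors = FALSE)
  profiles$level <- mapply(function(h, cond, d) {
    eff <- if (cond == "drought" && d > 0)
      hormone_effect_profile(cfg, d)[[h]] else 0
    2^(base[[h]] + eff)
  }, profiles$hormone, profiles$condition, profiles$day)
  list(hormones = hormones, profiles = profiles)
}

#' Simulate a full study dataset
#'
#' Convenience wrapper: design, expression, hormones, pathway table and
#' homolog map from one config.
#'
#' @param cfg a [sim_config()].
#' @return list with elements \code{design}, \code{expr}, \code{hormones},
#'   \code{pathways}, \code{homologs}, \code{truth}, \code{profiles}.
#' @export
simulate_study <- function(cfg) {
  cfg <- validate_sim_config(cfg)
  design <- generate_design(cfg)
  ex <- simulate_expression(cfg, design)
  ho <- simulate_hormones(cfg, design)
  ex$truth$hormone_profiles <- ho$profiles
  list(design = design, expr = ex$expr, hormones = ho$hormones,
       pathways = simulate_pathways(cfg), homologs = simulate_homologs(cfg),
       truth = ex$truth, profiles = ho$profiles)
}

#' Write a simulated dataset as a self-contained directory
#'
#' Emits expression.tsv, samples.tsv, hormones.tsv, pathways.tsv,
#' homologs.tsv and truth.json.
#'
#' @param study output of [simulate_study()] or [fig4_fixture()].
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression(study$expr, file.path(dir, "expression.tsv"))
  write_sample_sheet(study$design, file.path(dir, "samples.tsv"))
  write_hormones(study$hormones, file.path(dir, "hormones.tsv"))
  write_pathways(study$pathways, file.path(dir, "pathways.tsv"))
  write_homologs(study$homologs, file.path(dir, "homologs.tsv"))
  if (!is.null(study$truth))
    jsonlite::write_json(study$truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read back a dataset directory written by [write_study()]
#'
#' @param dir dataset directory.
#' @return list like [simulate_study()] (without \code{truth} if absent).
#' @export
read_study <- function(dir) {
  design <- read_sample_sheet(file.path(dir, "samples.tsv"))
  list(design = design,
       expr = read_expression(file.path(dir, "expression.tsv"), design),
       hormones = read_hormones(file.path(dir, "hormones.tsv"), design),
       pathways = read_pathways(file.path(dir, "pathways.tsv")),
       homologs = resolve_homologs(read_homologs(file.path(dir, "homologs.tsv"))))
}
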