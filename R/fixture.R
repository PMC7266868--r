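# Deterministic two-variety fixture whose drought networks reproduce the
# hub-centred sign structure: PP2C positively tied to ABF/SnRK2/GID,
# negatively to A-ARR/BZR, mixed with IAA (minority sign from BX only).

# n x p data whose SAMPLE correlation matrix equals C exactly: seeded
# normals are column-centred, orthonormalized (QR), then colored by
# chol(C). Requires p <= n - 1 and C positive definite.
exact_corr_data <- function(n, C, seed, sd = 1, means = 0) {
  p <- ncol(C)
  if (p > n - 1)
    dn_config_error("exact correlation needs p <= n - 1 (p=%d, n=%d)", p, n)
  Z <- with_seed(seed, matrix(stats::rnorm(n * p), n, p))
  Z <- scale(Z, center = TRUE, scale = FALSE)
  Q <- qr.Q(qr(Z))                     # orthonormal, mean-zero columns
  X <- Q %*% chol(C)
  X <- sweep(X, 2, sqrt(colSums(X^2) / (n - 1)), "/")   # unit sample sd
  sweep(X * sd, 2, rep_len(means, p), "+")
}

# Single-factor loadings per variety: hub 0.99, partners +/-0.82, so
# hub-partner sample Pearson is exactly 0.99*0.82 = 0.8118 (> 0.7) while
# partner-partner is exactly 0.82^2 = 0.6724 (< 0.7, no edge). IAA_2
# loads -0.82 in BX only (the mixed-sign PP2C-IAA edge with a B label);
# in K326 its loading 0.5 leaves the pair under threshold.
fixture_loadings <- function(variety) {
  c(PP2C_1 = 0.99, ABF_1 = 0.82, SNRK2_1 = 0.82, GID_1 = 0.82,
    AARR_1 = -0.82, BZR_1 = -0.82, IAA_1 = 0.82,
    IAA_2 = if (variety == "BX") -0.82 else 0.5)
}

fixture_pathways <- function() {
  data.frame(
    gene_id = c("PP2C_1", "ABF_1", "SNRK2_1", "GID_1", "AARR_1", "BZR_1",
                "IAA_1", "IAA_2",
                paste0("NOISE_", 1:6)),
    pathway = c("abscisic acid", "abscisic acid", "abscisic acid",
                "gibberellin", "cytokinin", "brassinosteroid",
                "auxin", "auxin", rep("", 6)),
    family = c("PP2C", "ABF", "SnRK2", "GID", "A-ARR", "BZR",
               "IAA", "IAA", rep("", 6)),
    stringsAsFactors = FALSE)
}

#' Deterministic fixture mirroring the published common-network topology
#'
#' A small two-variety dataset built so that, after the full pipeline
#' (DEG calling, per-condition consensus networks, family collapse,
#' cross-variety common network), the PP2C family node has strictly maximal
#' degree with positive edges to ABF, SnRK2 and GID, negative edges to
#' A-ARR and BZR, and a mixed-sign edge to IAA whose minority (negative)
#' component comes from variety BX only. Drought-sample correlations among
#' pathway genes are engineered exactly (single-factor structure, hub
#' loading 0.99, partner loadings 0.8: hub-partner r = 0.792 passes the
#' 0.7 consensus threshold, partner-partner r = 0.64 does not); control
#' correlations are exactly zero. Fully deterministic (hard-coded seed);
#' repeated calls are identical.
#'
#' @return list with \code{design}, \code{expr}, \code{hormones},
#'   \code{pathways}, \code{homologs} and \code{expected} (the planted
#'   family-level sign structure).
#' @param .seed internal; the frozen construction seed. The default was
#'   validated once so that every hub-pair Spearman rho also clears the
#'   0.7 threshold and no stray consensus edge reaches the common network;
#'   do not change it.
#' @export
fig4_fixture <- function(.seed = 20200534L) {
  seed <- as.integer(.seed)
  cfg <- sim_config(n_genes = 14L, n_pathway_genes = 8L, seed = seed)
  design <- generate_design(cfg)
  pw <- fixture_pathways()
  genes <- pw$gene_id
  path_genes <- genes[nzchar(pw$pathway)]
  mu <- stats::setNames(rep(5, length(genes)), genes)
  sd_e <- 0.35; shift <- 3

  lmat <- matrix(NA_real_, length(genes), nrow(design),
                 dimnames = list(genes, design$sample_id))
  for (vi in seq_along(cfg$varieties)) {
    v <- cfg$varieties[vi]
    ctl <- design$sample_id[design$variety == v & design$condition == "control"]
    trt <- design$sample_id[design$variety == v & design$condition == "drought"]
    lam <- fixture_loadings(v)
    C <- tcrossprod(lam) + diag(1 - lam^2)
    dimnames(C) <- list(names(lam), names(lam))
    # drought: exact single-factor correlation + signed DE shift
    Et <- exact_corr_data(length(trt), C, seed + 11L * vi)
    lmat[path_genes, trt] <- mu[path_genes] + sign(lam) * shift +
      t(Et) * sd_e
    # control (incl shared d0): exactly uncorrelated residuals
    Ec <- exact_corr_data(length(ctl), diag(length(path_genes)),
                          seed + 101L * vi)
    lmat[path_genes, ctl] <- mu[path_genes] + t(Ec) * sd_e
    # filler genes: plain seeded noise, no DE, both conditions
    noise <- with_seed(seed + 1009L * vi,
                       matrix(stats::rnorm(6 * (length(ctl) + length(trt)),
                                           0, sd_e), nrow = 6))
    lmat[paste0("NOISE_", 1:6), c(ctl, trt)] <-
      mu[paste0("NOISE_", 1:6)] + noise
  }
  expr <- pmax(2^lmat - 1, 0)

  H <- names(hormone_baselines)
  hnoise <- with_seed(seed + 31L,
                      matrix(stats::rnorm(length(H) * nrow(design), 0, sd_e),
                             nrow = length(H)))
  hormones <- 2^(log2(hormone_baselines) + hnoise)
  dimnames(hormones) <- list(H, design$sample_id)

  homologs <- resolve_homologs(
    data.frame(gene_id_v1 = genes, gene_id_v2 = genes, similarity = 1,
               stringsAsFactors = FALSE))
  expected <- data.frame(
    family_a = c("ABF", "PP2C", "GID", "A-ARR", "BZR", "IAA"),
    family_b = c("PP2C", "SnRK2", "PP2C", "PP2C", "PP2C", "PP2C"),
    sign = c("+", "+", "+", "-", "-", "mixed"),
    stringsAsFactors = FALSE)
  list(design = design, expr = expr, hormones = hormones, pathways = pw,
       homologs = homologs, expected = expected, hub_family = "PP2C")
}
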