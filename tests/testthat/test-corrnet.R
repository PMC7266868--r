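test_that("pearson_with_p: exact cases and the direct-formula oracle", {
  res <- pearson_with_p(1:5, 2 * (1:5))
  expect_equal(res$r, 1)
  expect_equal(res$p, 0)
  expect_equal(pearson_with_p(c(1, 2, 3), c(3, 2, 1))$r, -1)
  set.seed(7)
  for (i in 1:50) {
    x <- rnorm(15); y <- rnorm(15)
    got <- pearson_with_p(x, y)
    want <- oracle_pearson(x, y)
    expect_equal(got$r, want$r, tolerance = 1e-12)
    expect_equal(got$p, want$p, tolerance = 1e-12)
  }
  expect_error(pearson_with_p(1:2, 1:2), class = "dn_input_error")
  expect_warning(res <- pearson_with_p(rep(1, 5), rnorm(5)), "zero variance")
  expect_true(is.na(res$r))
})

test_that("spearman_with_p: mid-ranks, monotone invariance, symmetry", {
  x <- sort(rnorm(10))
  expect_equal(spearman_with_p(x, exp(x))$rho, 1)
  got <- spearman_with_p(c(1, 1, 2), c(1, 2, 3))
  want <- oracle_spearman(c(1, 1, 2), c(1, 2, 3))
  expect_equal(got$rho, want$rho, tolerance = 1e-12)
  set.seed(8)
  for (i in 1:30) {
    x <- sample(1:6, 12, replace = TRUE)   # heavy ties
    y <- rnorm(12)
    a <- spearman_with_p(x, y); b <- spearman_with_p(y, x)
    expect_equal(a$rho, b$rho, tolerance = 1e-12)
    w <- oracle_spearman(x, y)
    expect_equal(a$rho, w$rho, tolerance = 1e-12)
    expect_equal(a$p, w$p, tolerance = 1e-12)
  }
})

test_that("matrix and scalar correlation paths agree", {
  # regression test: matrix p-values must keep their shape/alignment
  set.seed(11)
  m <- matrix(rnorm(12 * 5), 12, 5, dimnames = list(NULL, letters[1:5]))
  cc <- droughtnet:::cor_all_pairs(m)
  for (i in 1:4) for (j in (i + 1):5) {
    w <- oracle_pearson(m[, i], m[, j])
    expect_equal(cc$r[i, j], w$r, tolerance = 1e-12)
    expect_equal(cc$p_r[i, j], w$p, tolerance = 1e-12)
    ws <- oracle_spearman(m[, i], m[, j])
    expect_equal(cc$rho[i, j], ws$rho, tolerance = 1e-12)
    expect_equal(cc$p_rho[i, j], ws$p, tolerance = 1e-12)
  }
})

test_that("zscore_rows: conventions and identities", {
  expect_equal(zscore_rows(matrix(c(1, 1, 1), 1)), matrix(0, 1, 3))
  z <- zscore_rows(matrix(c(0, 3), 1))
  expect_equal(as.vector(z), c(-0.7071068, 0.7071068), tolerance = 1e-6)
  set.seed(3)
  m <- matrix(runif(50, 0, 100), 5)
  z <- zscore_rows(m)
  expect_lt(max(abs(rowMeans(z))), 1e-9)
  expect_lt(max(abs(apply(z, 1, sd) - 1)), 1e-9)
})

test_that("n = 5 threshold consistency: |r| <= 0.878 never significant", {
  set.seed(5)
  for (i in 1:200) {
    x <- rnorm(5); y <- rnorm(5)
    res <- pearson_with_p(x, y)
    if (abs(res$r) <= 0.878) expect_gte(res$p, 0.05)
  }
})

test_that("build_network applies the consensus rule on both methods", {
  cfg <- tiny_config(seed = 41)
  st <- simulate_study(cfg)
  dg <- deg_union(call_degs(st$expr, st$design, "K326"))
  net <- build_network(st$expr, st$hormones, st$pathways, dg,
                       st$design, "K326", "drought")
  expect_s3_class(net, "dn_network")
  p <- net$pairs
  manual <- abs(p$pearson_r) > 0.7 & p$pearson_p < 0.05 &
    abs(p$spearman_rho) > 0.7 & p$spearman_p < 0.05
  expect_identical(p$passes, manual)
  expect_equal(nrow(net$edges), sum(manual))
  expect_true(all(net$edges$node_a < net$edges$node_b))
  expect_true(all(net$edges$sign == ifelse(net$edges$pearson_r >= 0,
                                           "+", "-")))
  # a pair passing Pearson but not Spearman is not an edge by construction
  one_method <- abs(p$pearson_r) > 0.7 & p$pearson_p < 0.05 &
    !(abs(p$spearman_rho) > 0.7 & p$spearman_p < 0.05)
  if (any(one_method)) expect_false(any(p$passes[one_method]))
})

test_that("consensus network is a subset of each single-method network", {
  for (s in 1:30) {
    set.seed(s)
    m <- matrix(rnorm(10 * 8), 10, 8, dimnames = list(NULL, letters[1:8]))
    cc <- droughtnet:::cor_all_pairs(m)
    up <- upper.tri(cc$r)
    consensus <- abs(cc$r[up]) > 0.7 & cc$p_r[up] < 0.05 &
      abs(cc$rho[up]) > 0.7 & cc$p_rho[up] < 0.05
    pearson_only <- abs(cc$r[up]) > 0.7 & cc$p_r[up] < 0.05
    spearman_only <- abs(cc$rho[up]) > 0.7 & cc$p_rho[up] < 0.05
    expect_true(all(consensus <= pearson_only))
    expect_true(all(consensus <= spearman_only))
  }
})

test_that("edge set is invariant under joint sample reordering", {
  cfg <- tiny_config(seed = 43)
  st <- simulate_study(cfg)
  dg <- deg_union(call_degs(st$expr, st$design, "K326"))
  net1 <- build_network(st$expr, st$hormones, st$pathways, dg,
                        st$design, "K326", "drought")
  set.seed(1)
  perm <- sample(ncol(st$expr))
  net2 <- build_network(st$expr[, perm], st$hormones[, perm], st$pathways,
                        dg, st$design, "K326", "drought")
  key <- function(n) paste(n$edges$node_a, n$edges$node_b)
  expect_setequal(key(net1), key(net2))
})

test_that("degenerate networks are handled", {
  cfg <- tiny_config(seed = 44)
  st <- simulate_study(cfg)
  expect_error(build_network(st$expr, st$hormones, st$pathways, "G0001",
                             st$design, "nosuch", "drought"),
               class = "dn_input_error")
  # constant node dropped with a warning
  expr2 <- st$expr
  expr2["G0002", ] <- 7
  dg <- c("G0001", "G0002")
  expect_warning(
    net <- build_network(expr2, NULL, st$pathways, dg, st$design,
                         "K326", "drought"),
    "constant")
  expect_false("G0002" %in% net$nodes$node)
})

test_that("per-stage-means mode correlates day means", {
  cfg <- tiny_config(seed = 45)
  st <- simulate_study(cfg)
  dg <- deg_union(call_degs(st$expr, st$design, "K326"))
  net <- build_network(st$expr, st$hormones, st$pathways, dg,
                       st$design, "K326", "drought",
                       per_stage_means = TRUE)
  expect_equal(net$n_samples, 4L)   # 4 treated days
})
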