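mknet <- function(edges, variety = "v", condition = "drought") {
  structure(list(variety = variety, condition = condition, edges = edges),
            class = "dn_network")
}

edge_row <- function(a, b, r = 0.8) {
  data.frame(node_a = pmin(a, b), node_b = pmax(a, b), pearson_r = r,
             pearson_p = 0.01, spearman_rho = r, spearman_p = 0.01,
             sign = ifelse(r >= 0, "+", "-"), stringsAsFactors = FALSE)
}

test_that("differential_edges classifies by endpoint pair", {
  e <- rbind(edge_row("A", "B"), edge_row("B", "C"))
  d <- differential_edges(mknet(e, condition = "control"), mknet(e))
  expect_equal(nrow(d$gained), 0L)
  expect_equal(nrow(d$lost), 0L)
  expect_equal(nrow(d$stable), 2L)

  d2 <- differential_edges(mknet(edge_row("A", "B"), condition = "control"),
                           mknet(edge_row("C", "D")))
  expect_equal(nrow(d2$stable), 0L)
  expect_equal(d2$gained$node_a, "C")
  expect_equal(d2$lost$node_a, "A")

  expect_error(differential_edges(mknet(e, variety = "v1"),
                                  mknet(e, variety = "v2")),
               class = "dn_input_error")

  # random networks equal brute-force set algebra, and the three sets
  # partition the union
  nodes <- paste0("n", 1:8)
  for (s in 1:15) {
    ec <- edge_row("x", "y")[0, ]
    ec <- random_edge_df(nodes, 12, s)
    ed <- random_edge_df(nodes, 12, s + 100)
    kc <- paste(ec$node_a, ec$node_b); kd <- paste(ed$node_a, ed$node_b)
    d <- differential_edges(mknet(ec, condition = "control"), mknet(ed))
    kg <- paste(d$gained$node_a, d$gained$node_b)
    kl <- paste(d$lost$node_a, d$lost$node_b)
    ks <- paste(d$stable$node_a, d$stable$node_b)
    expect_setequal(kg, setdiff(kd, kc))
    expect_setequal(kl, setdiff(kc, kd))
    expect_setequal(ks, intersect(kc, kd))
    expect_length(intersect(kg, c(kl, ks)), 0)
    expect_setequal(c(kg, kl, ks), union(kc, kd))
  }
})

pw_families <- data.frame(
  gene_id = c("PP2Cg1", "PP2Cg7", "ABFg1", "ABFg3", "IAAg1", "IAAg2",
              "orphan"),
  pathway = c(rep("abscisic acid", 4), "auxin", "auxin", "auxin"),
  family = c("PP2C", "PP2C", "ABF", "ABF", "AUX/IAA", "AUX/IAA", ""),
  stringsAsFactors = FALSE)

test_that("collapse_to_family groups by family pair and sign", {
  e <- rbind(edge_row("PP2Cg1", "ABFg1", 0.8),
             edge_row("PP2Cg7", "ABFg3", 0.9))
  f <- collapse_to_family(e, pw_families)
  expect_equal(nrow(f), 1L)
  expect_equal(f$mean_pos, 0.85)
  expect_equal(f$sign, "+")
  expect_equal(f$mean_coefficient, 0.85)

  single <- collapse_to_family(edge_row("PP2Cg1", "IAAg1", 0.77),
                               pw_families)
  expect_equal(single$mean_coefficient, 0.77)

  mixed <- collapse_to_family(rbind(edge_row("PP2Cg1", "IAAg1", 0.8),
                                    edge_row("PP2Cg7", "IAAg2", -0.75)),
                              pw_families)
  expect_equal(mixed$sign, "mixed")
  expect_equal(mixed$mean_pos, 0.8)
  expect_equal(mixed$mean_neg, -0.75)
  expect_true(is.na(mixed$mean_coefficient))

  # hormone endpoints stand for themselves; unannotated genes are dropped
  expect_warning(
    f2 <- collapse_to_family(rbind(edge_row("PP2Cg1", "ABA", 0.9),
                                   edge_row("orphan", "ABFg1", 0.9)),
                             pw_families),
    "orphan")
  expect_equal(nrow(f2), 1L)
  expect_setequal(c(f2$family_a, f2$family_b), c("ABA", "PP2C"))

  # within-family edges collapse to self-loops and are dropped
  expect_equal(nrow(collapse_to_family(edge_row("PP2Cg1", "PP2Cg7", 0.9),
                                       pw_families)), 0L)

  # idempotence: collapsing an already family-level edge set is identity
  fam_edges <- data.frame(node_a = c("ABF", "AUX/IAA"),
                          node_b = c("PP2C", "PP2C"),
                          pearson_r = c(0.85, -0.7),
                          stringsAsFactors = FALSE)
  f3 <- collapse_to_family(fam_edges, pw_families)
  expect_equal(f3$family_a, fam_edges$node_a)
  expect_equal(f3$family_b, fam_edges$node_b)
  expect_equal(f3$mean_coefficient, fam_edges$pearson_r)
})

test_that("common_network requires presence in both varieties", {
  n1 <- mknet(rbind(edge_row("PP2Cg1", "ABFg1", 0.8),
                    edge_row("PP2Cg1", "IAAg1", 0.75)), variety = "K")
  n2 <- mknet(rbind(edge_row("PP2Cg7", "ABFg3", 0.9)), variety = "B")
  cm <- common_network(n1, n2, pw_families)
  expect_s3_class(cm, "dn_common")
  expect_equal(nrow(cm$edges), 1L)
  expect_equal(cm$edges$family_a, "ABF")
  expect_equal(cm$edges$family_b, "PP2C")
  expect_equal(cm$edges$mean_pos, 0.85)
  expect_equal(cm$edges$sign, "+")

  # mixed edge: v1 contributes + and -, v2 contributes + only ->
  # minority-sign label is v1's
  n1b <- mknet(rbind(edge_row("PP2Cg1", "IAAg1", 0.8),
                     edge_row("PP2Cg7", "IAAg2", -0.75)), variety = "K")
  n2b <- mknet(edge_row("PP2Cg1", "IAAg1", 0.9), variety = "B")
  cmb <- common_network(n1b, n2b, pw_families)
  expect_equal(cmb$edges$sign, "mixed")
  expect_equal(cmb$edges$variety_labels, "K")
  expect_equal(cmb$edges$mean_pos, 0.85)
  expect_equal(cmb$edges$mean_neg, -0.75)
})

test_that("common network modes nest and stay within each variety", {
  cfg <- tiny_config(seed = 51)
  st <- simulate_study(cfg)
  res <- suppressWarnings(run_pipeline(st$expr, st$design, st$hormones,
                                       st$pathways, st$homologs))
  present <- res$common
  specific <- common_network(res$networks$K326$drought,
                             res$networks$BX$drought,
                             st$pathways, mode = "drought-specific",
                             diff_v1 = res$diff$K326, diff_v2 = res$diff$BX)
  keyify <- function(cm) paste(cm$edges$family_a, cm$edges$family_b)
  expect_true(all(keyify(specific) %in% keyify(present)))
  for (v in c("K326", "BX")) {
    fam <- collapse_to_family(res$networks[[v]]$drought$edges, st$pathways)
    expect_true(all(keyify(present) %in% paste(fam$family_a, fam$family_b)))
  }
})
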