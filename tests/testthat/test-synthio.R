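test_that("generate_design enumerates the shared-d0 design", {
  # 2 varieties x (1 shared d0 + 4 days x 2 conditions) x 3 reps = 54
  expect_equal(nrow(generate_design(tiny_config())), 54L)
  one <- sim_config(varieties = "V", conditions = "control", days = 0L,
                    n_replicates = 1L, n_genes = 10, n_pathway_genes = 2,
                    hub_partners = character(0))
  expect_equal(nrow(generate_design(one)), 1L)
  expect_error(sim_config(days = c(5L, 2L)), class = "dn_config_error")
  expect_error(sim_config(days = c(2L, 5L)), class = "dn_config_error") # no d0
  expect_error(sim_config(n_replicates = 1L), class = "dn_config_error")
  expect_error(sim_config(planted_r = 0.6), class = "dn_config_error")
  expect_error(sim_config(deg_log2fc = 0.5), class = "dn_config_error")
})

test_that("simulation is reproducible and FPKM-valid", {
  cfg <- tiny_config(seed = 7)
  st1 <- simulate_study(cfg)
  st2 <- simulate_study(cfg)
  expect_identical(st1$expr, st2$expr)
  expect_identical(st1$hormones, st2$hormones)
  expect_true(all(st1$expr >= 0))
  expect_true(all(st1$hormones > 0))
  st3 <- simulate_study(tiny_config(seed = 8))
  expect_false(identical(st1$expr, st3$expr))
})

test_that("noiseless limit: planted DEG mean ratio equals 2^deg_log2fc", {
  cfg <- sim_config(n_genes = 20, n_pathway_genes = 5, dispersion = 1e-6,
                    deg_log2fc = 2, deg_fraction = 0.5, planted_r = 0.95,
                    hub_partners = c(G0002 = "+"), seed = 3)
  design <- generate_design(cfg)
  sim <- simulate_expression(cfg, design)
  # the hub gene has a high baseline, where the FPKM = 2^x - 1 floor
  # offset is negligible and the idealized ratio 2^deg_log2fc holds
  up <- sim$truth$hub
  trt <- design$sample_id[design$variety == "K326" &
                            design$condition == "drought" & design$day == 5]
  ctl <- design$sample_id[design$variety == "K326" &
                            design$condition == "control" & design$day == 5]
  # remove the deterministic trajectory component at d5 before comparing
  ratio <- mean(sim$expr[up, trt]) / mean(sim$expr[up, ctl]) /
    2^sim$truth$factor[["K326 5"]]
  expect_equal(ratio, 4, tolerance = 0.02)
})

test_that("planted drought correlation separates from control", {
  # Monte-Carlo with the independent correlation oracle: hub-partner
  # sample r under drought > 0.7 in >= 95/100 runs, under control
  # |r| > 0.7 in <= 10/100 runs
  hit_d <- hit_c <- 0
  for (s in 1:100) {
    cfg <- sim_config(n_genes = 12, n_pathway_genes = 10, seed = 4000 + s,
                      hub_partners = c(G0002 = "+", G0003 = "-"))
    design <- generate_design(cfg)
    sim <- simulate_expression(cfg, design)
    lm2 <- log2(sim$expr + 1)
    ds <- samples_for(design, "K326", "drought")$sample_id
    cs <- samples_for(design, "K326", "control")$sample_id
    rd <- oracle_pearson(lm2["G0001", ds], lm2["G0002", ds])$r
    rc <- oracle_pearson(lm2["G0001", cs], lm2["G0002", cs])$r
    if (rd > 0.7) hit_d <- hit_d + 1
    if (abs(rc) > 0.7) hit_c <- hit_c + 1
  }
  expect_gte(hit_d, 95)
  expect_lte(hit_c, 10)
})

test_that("hormone profiles have the planted qualitative shape", {
  cfg <- tiny_config(seed = 11)
  design <- generate_design(cfg)
  ho <- simulate_hormones(cfg, design)
  expect_true(all(ho$hormones > 0))
  expect_setequal(rownames(ho$hormones),
                  c("ZR", "IAA", "GA3", "ABA", "BR", "JA-me"))
  pr <- ho$profiles
  lvl <- function(h, cond, d)
    pr$level[pr$hormone == h & pr$condition == cond & pr$day == d]
  for (d in c(2, 5, 15)) expect_gt(lvl("ABA", "drought", d),
                                   lvl("ABA", "control", d))
  for (d in c(5, 15, 30)) expect_gt(lvl("IAA", "drought", d),
                                    lvl("IAA", "control", d))

  # noiseless limit: ABA drought/control ratio at d2 is the configured one
  cfg0 <- sim_config(n_genes = 10, n_pathway_genes = 2, dispersion = 1e-9,
                     hub_partners = character(0), aba_effect = 3, seed = 5)
  d0 <- generate_design(cfg0)
  h0 <- simulate_hormones(cfg0, d0)
  trt <- d0$sample_id[d0$condition == "drought" & d0$day == 2]
  ctl <- d0$sample_id[d0$condition == "control" & d0$day == 2]
  expect_equal(mean(h0$hormones["ABA", trt]) / mean(h0$hormones["ABA", ctl]),
               3, tolerance = 1e-4)
})

test_that("optional ABA coupling plants a positive ABA-hub correlation", {
  hits <- 0
  for (s in 1:30) {
    cfg <- sim_config(n_genes = 12, n_pathway_genes = 10, couple_aba = TRUE,
                      hub_partners = c(G0002 = "+"), seed = 6000 + s)
    design <- generate_design(cfg)
    sim <- simulate_expression(cfg, design)
    ho <- simulate_hormones(cfg, design)
    ds <- samples_for(design, "K326", "drought")$sample_id
    r <- oracle_pearson(log2(sim$expr["G0001", ds] + 1),
                        log2(ho$hormones["ABA", ds]))$r
    if (r > 0.7) hits <- hits + 1
  }
  expect_gte(hits, 27)
})

test_that("truth bookkeeping matches the planted structure", {
  cfg <- tiny_config(seed = 13)
  st <- simulate_study(cfg)
  tr <- st$truth
  # planted edges are symmetric-canonical and hub-centred
  expect_true(all(tr$planted_edges$node_a < tr$planted_edges$node_b))
  in_edges <- c(tr$planted_edges$node_a, tr$planted_edges$node_b)
  expect_gt(sum(in_edges == tr$hub), max(table(in_edges[in_edges != tr$hub])))
  # per-variety per-stage truth carries the realized module effects
  expect_named(tr$deg_genes, cfg$varieties)
  expect_true(all(abs(tr$deg_genes$K326$d2$log2fc) >= 1))
})

test_that("study directories round-trip through write_study/read_study", {
  tmp <- withr::local_tempdir()
  st <- simulate_study(tiny_config(seed = 17))
  write_study(st, tmp)
  expect_true(all(file.exists(file.path(tmp,
    c("expression.tsv", "samples.tsv", "hormones.tsv", "pathways.tsv",
      "homologs.tsv", "truth.json")))))
  back <- read_study(tmp)
  expect_lt(max(abs(back$expr - st$expr)), 1e-9)
  expect_identical(back$design$sample_id, st$design$sample_id)
  expect_identical(back$pathways$family, st$pathways$family)
})
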