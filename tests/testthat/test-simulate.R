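test_that("simulation is seed-deterministic and respects the config", {
  cfg <- sim_config(n_genes = 200, hub_size = 5, seed = 42)
  ds1 <- simulate_dataset(cfg)
  ds2 <- simulate_dataset(cfg)
  expect_identical(ds1$matrix$values, ds2$matrix$values)
  expect_identical(ds1$truth, ds2$truth)

  ds3 <- simulate_dataset(sim_config(n_genes = 200, hub_size = 5, seed = 43))
  expect_false(identical(ds1$matrix$values, ds3$matrix$values))

  expect_true(all(ds1$matrix$values > 0))
  expect_equal(dim(ds1$matrix$values), c(200, 9))
  expect_equal(nrow(ds1$truth), 200)
  # planted fractions realized
  expect_equal(sum(ds1$truth$profile == 5, na.rm = TRUE), 20)
  expect_equal(sum(ds1$truth$profile == 2, na.rm = TRUE), 10)
  expect_equal(sum(is.na(ds1$truth$profile)), 200 - 40)
})

test_that("true group means follow baseline + effect * profile position", {
  cfg <- sim_config(n_genes = 100, profile_fractions = c("7" = 0.2),
                    effect_size = 1.5, baseline_log2_mean = 6,
                    hub_size = 0, seed = 5)
  ds <- simulate_dataset(cfg)
  planted <- !is.na(ds$truth$profile)
  # profile 7 positions are (0, 1, 2)
  expect_equal(unique(ds$truth$mean_control[planted]), 6)
  expect_equal(unique(ds$truth$mean_OVA[planted]), 6 + 1.5)
  expect_equal(unique(ds$truth$mean_4w_after[planted]), 6 + 3)
  expect_true(all(ds$truth$mean_OVA[!planted] == 6))
})

test_that("zero effect size leaves profiles in the truth but data null", {
  cfg <- sim_config(n_genes = 400, profile_fractions = c("5" = 0.5),
                    effect_size = 0, hub_size = 0, seed = 9)
  ds <- simulate_dataset(cfg)
  expect_equal(sum(ds$truth$profile == 5, na.rm = TRUE), 200)
  gm <- ds$truth[, c("mean_control", "mean_OVA", "mean_4w_after")]
  expect_true(all(gm == gm[[1]][1]))
})

test_that("per-gene sample variances follow the inverse-gamma prior", {
  # under the model, s2 * a * b ~ F(d, 2a); check the full fitted-form
  # distribution by Kolmogorov-Smirnov at large G
  a <- 2; b <- 1
  cfg <- sim_config(n_genes = 10000, profile_fractions = NULL,
                    variance_prior_shape = a, variance_prior_scale = b,
                    hub_size = 0, seed = 31)
  ds <- simulate_dataset(cfg)
  s2 <- stcnet:::residual_variances(ds$matrix)
  d <- 9 - 3
  ks <- suppressWarnings(ks.test(s2 * a * b, "pf", d, 2 * a))
  expect_gt(ks$p.value, 0.01)
  # truth table variances really are the generating variances
  expect_gt(cor(ds$truth$variance, s2), 0.5)
})

test_that("config validation rejects impossible designs", {
  expect_error(sim_config(groups = "only_one"), "2 ordered groups")
  expect_error(sim_config(profile_fractions = c("5" = 0.7, "2" = 0.5)),
               "sum to <= 1")
  expect_error(sim_config(profile_fractions = c("9" = 0.1)), "invalid profile")
  expect_error(sim_config(variance_prior_shape = 0), "positive")
  expect_error(sim_config(effect_size = -1), ">= 0")
  expect_error(sim_config(n_genes = 0), ">= 1")
})

test_that("hub module genes share the designated hub's fluctuations", {
  cfg <- sim_config(n_genes = 500, seed = 17)
  ds <- simulate_dataset(cfg)
  hub <- ds$truth$gene[ds$truth$is_hub]
  spokes <- ds$truth$gene[ds$truth$is_spoke]
  expect_length(hub, 1)
  expect_length(spokes, 40)
  expect_true(all(ds$truth$profile[ds$truth$is_spoke] == 5))
  L <- log2(ds$matrix$values)
  hub_cors <- cor(L[hub, ], t(L[spokes, ]))
  expect_true(all(hub_cors > 0.9))
  # the hub's centered latent leaves its group means exactly on the profile
  gm <- rowMeans(L[hub, 1:3, drop = FALSE])
  expect_equal(mean(L[hub, 1:3]), ds$truth$mean_control[ds$truth$is_hub],
               tolerance = 1e-12)
  expect_equal(mean(L[hub, 4:6]), ds$truth$mean_OVA[ds$truth$is_hub],
               tolerance = 1e-12)
})

test_that("simulated gene sets plant enriched sets and round-trip as GMT", {
  ds <- simulate_dataset(sim_config(n_genes = 500, seed = 8))
  coll <- simulate_gene_sets(ds$truth, n_sets = 10, set_size = 30,
                             planted = 5, seed = 2)
  expect_length(coll, 11)
  planted_set <- coll$sets[["planted_profile_5"]]$genes
  prof5 <- ds$truth$gene[!is.na(ds$truth$profile) & ds$truth$profile == 5]
  expect_gte(length(intersect(planted_set, prof5)), ceiling(0.8 * 30))

  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(coll, path)
  back <- read_gmt(path, universe = coll$universe)
  expect_identical(lapply(back$sets, `[[`, "genes"),
                   lapply(coll$sets, `[[`, "genes"))

  # empty collection is still a valid (zero-record) GMT
  empty <- simulate_gene_sets(ds$truth, n_sets = 0, set_size = 10, seed = 1)
  expect_length(empty, 0)
  p2 <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(empty, p2)
  expect_identical(readLines(p2), character(0))

  expect_error(simulate_gene_sets(ds$truth[0, ], 1, 5), "empty truth")
  expect_error(simulate_gene_sets(ds$truth, 1, 5, planted = 7),
               "no genes planted on profile 7")
})

test_that("random gene sets are null against a random gene list", {
  # Fisher p over random set/list pairs should be roughly uniform:
  # check the rejection rate at 0.05 over many draws
  ds <- simulate_dataset(sim_config(n_genes = 400, profile_fractions = NULL,
                                    hub_size = 0, seed = 12))
  set.seed(99)
  ps <- replicate(300, {
    coll_genes <- sample(ds$truth$gene, 40)
    lst <- sample(ds$truth$gene, 50)
    test_gene_set(lst, coll_genes, ds$truth$gene)$fisher_p
  })
  expect_lt(mean(ps < 0.05), 0.09)
  expect_gt(mean(ps < 0.5), 0.3)
})

test_that("random graphs hit the degenerate corners and are reproducible", {
  g1 <- simulate_random_graph(4, 1, seed = 1)
  m1 <- node_metrics(g1)
  expect_true(all(m1$degree == 3))
  expect_true(all(m1$clustering == 1))
  expect_true(all(m1$kcore == 3))

  g0 <- simulate_random_graph(10, 0, seed = 1)
  expect_equal(nrow(g0$edges), 0)
  expect_true(all(node_metrics(g0)$degree == 0))

  ga <- simulate_random_graph(30, 0.2, seed = 7)
  gb <- simulate_random_graph(30, 0.2, seed = 7)
  expect_identical(ga$edges, gb$edges)
  expect_error(simulate_random_graph(0, 0.5), "n_nodes")
  expect_error(simulate_random_graph(5, 1.2), "edge_prob")
})
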