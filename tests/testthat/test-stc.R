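test_that("profile enumeration is complete, dense and lexicographic", {
  p31 <- enumerate_profiles(3, 1)
  expect_equal(nrow(p31), 8)
  expect_equal(p31$id, 0:7)
  # the adopted numbering: ids 0-2 down-first, 3-4 flat-first, 5-7 up-first
  expect_equal(p31$change_1, c(-1, -1, -1, 0, 0, 1, 1, 1))
  expect_equal(p31$change_2, c(-1, 0, 1, -1, 1, -1, 0, 1))
  # trend semantics used throughout: 5 = up then back down, 6 = up then
  # sustained, 7 = steadily up
  pv <- stcnet:::profile_positions(p31)
  expect_equal(unname(pv[p31$id == 5, ]), c(0, 1, 0))
  expect_equal(unname(pv[p31$id == 6, ]), c(0, 1, 1))
  expect_equal(unname(pv[p31$id == 7, ]), c(0, 1, 2))
  expect_equal(unname(pv[p31$id == 0, ]), c(0, -1, -2))
  expect_true(all(pv[, 1] == 0))

  expect_equal(nrow(enumerate_profiles(2, 1)), 2)
  expect_equal(nrow(enumerate_profiles(3, 2)), 24)
  expect_equal(nrow(enumerate_profiles(4, 1)), 26)
  expect_error(enumerate_profiles(1, 1), "m >= 2")
  expect_error(enumerate_profiles(3, 0), "c must be >= 1")
})

test_that("log-ratio transform anchors at the first-group geometric mean", {
  em <- make_em(rbind(g1 = log2(c(4, 8, 2))), n_rep = 3)
  r <- transform_to_log_ratios(em)
  expect_equal(unname(r[1, ]), c(0, 1, -1))

  # geometric mean of replicates (1, 2, 4) is 2
  L <- rbind(g1 = log2(c(1, 2, 4, 4, 4, 4)))
  colnames(L) <- paste0("s", 1:6)
  design <- data.frame(sample = colnames(L),
                       group = factor(rep(c("A", "B"), each = 3)))
  em2 <- expr_matrix(2^L, design)
  r2 <- transform_to_log_ratios(em2)
  expect_equal(unname(r2[1, ]), c(0, log2(4 / 2)))

  # log identity: ratio = mean of replicate log2 values minus group-1 mean
  set.seed(21)
  em3 <- make_em(matrix(rnorm(60, 8), 20, 3), n_rep = 3, sd = 0.5, seed = 21)
  r3 <- transform_to_log_ratios(em3)
  L3 <- log2(em3$values)
  manual <- sapply(1:3, function(k)
    rowMeans(L3[, (3 * k - 2):(3 * k)])) - rowMeans(L3[, 1:3])
  expect_equal(unname(r3), unname(manual), tolerance = 1e-12)
})

test_that("genes go to the best-correlated profile, ties to the lowest id", {
  p <- enumerate_profiles(3, 1)
  ratios <- rbind(down2 = c(0, -2, -4),    # exact multiple of profile 0
                  spike = c(0, 1.8, 0.1),
                  flat  = c(0, 0, 0))
  a <- assign_profiles(ratios, p)
  expect_equal(a$profile[1], 0L)
  expect_equal(a$cor[1], 1)
  # brute-force argmax over the 8 profile correlations
  pv <- stcnet:::profile_positions(p)
  cors <- apply(pv, 1, function(v) cor(c(0, 1.8, 0.1), v))
  expect_equal(a$profile[2], p$id[which.max(cors)])
  expect_equal(a$profile[2], 5L)
  expect_true(is.na(a$profile[3]))
  expect_true(is.na(a$cor[3]))

  # scale invariance of assignment
  a2 <- assign_profiles(ratios * 3.7, p)
  expect_equal(a2$profile, a$profile)

  expect_error(assign_profiles(ratios[, 1:2], p), "m = 3")

  # (0, -1, 1) correlates 0.866 with both profile 2 (0,-1,0) and
  # profile 4 (0,0,1): the tie goes to the lower id
  tie <- assign_profiles(rbind(t1 = c(0, -1, 1)), p)
  expect_equal(tie$profile, 2L)
})

test_that("every gene is assigned to exactly one profile or left out", {
  ds <- simulate_dataset(sim_config(n_genes = 300, hub_size = 0, seed = 14))
  em <- ds$matrix
  p <- enumerate_profiles(3, 1)
  a <- assign_profiles(transform_to_log_ratios(em), p)
  expect_equal(nrow(a), 300)
  expect_true(all(is.na(a$profile) | a$profile %in% p$id))
  s <- profile_significance(a)
  expect_equal(sum(s$observed) + attr(s, "unassigned"), 300)
})

test_that("permutation significance evaluates all orderings and flags excess", {
  p <- enumerate_profiles(3, 1)
  # genes exactly on profile 7 positions with distinct magnitudes
  set.seed(2)
  mags <- runif(40, 0.5, 2)
  ratios <- cbind(0, mags, 2 * mags)
  rownames(ratios) <- sprintf("g%02d", 1:40)
  a <- assign_profiles(ratios, p)
  expect_true(all(a$profile == 7))
  s <- profile_significance(a)
  expect_equal(attr(s, "n_orderings"), 6)
  expect_equal(s$observed[s$profile == 7], 40)
  expect_lt(s$expected[s$profile == 7], 40)
  expect_lt(s$p[s$profile == 7], 0.05)
  expect_true(s$significant[s$profile == 7])

  # a profile whose observed count equals its expectation is not in excess
  even <- s[s$observed == round(s$expected) & s$profile != 7, ]
  expect_true(all(even$p >= 0.5))

  # binomial alternative agrees on the call
  sb <- profile_significance(a, method = "binomial")
  expect_true(sb$significant[sb$profile == 7])
})

test_that("planted profiles are recovered and are the ones called", {
  # effect 1.0 log2/step, sd ~0.25: tight prior around variance 0.0625
  correct <- 0; total <- 0; clean_calls <- 0
  n_seeds <- 25
  for (s in seq_len(n_seeds)) {
    cfg <- sim_config(n_genes = 400,
                      profile_fractions = c("5" = 0.1, "2" = 0.1),
                      effect_size = 1.0,
                      variance_prior_shape = 50,
                      variance_prior_scale = 16 / 49,
                      hub_size = 0, seed = 1000 + s)
    ds <- simulate_dataset(cfg)
    p <- enumerate_profiles(3, 1)
    planted <- !is.na(ds$truth$profile)
    ratios <- transform_to_log_ratios(subset_genes(ds$matrix,
                                                   ds$truth$gene[planted]))
    a <- assign_profiles(ratios, p)
    correct <- correct + sum(a$profile == ds$truth$profile[planted],
                             na.rm = TRUE)
    total <- total + sum(planted)
    sig <- profile_significance(a)
    called <- sort(sig$profile[sig$significant])
    if (identical(called, c(2L, 5L))) clean_calls <- clean_calls + 1
  }
  expect_gte(correct / total, 0.9)
  expect_gte(clean_calls / n_seeds, 0.9)
})

test_that("null data produce no systematic profile excess", {
  # flat genes + noise: observed tracks expected; few profiles called
  n_sig <- 0; n_profiles <- 0
  for (s in 1:20) {
    ds <- simulate_dataset(sim_config(n_genes = 200,
                                      profile_fractions = NULL,
                                      hub_size = 0, seed = 2000 + s))
    p <- enumerate_profiles(3, 1)
    a <- assign_profiles(transform_to_log_ratios(ds$matrix), p)
    sig <- profile_significance(a)
    n_sig <- n_sig + sum(sig$significant)
    n_profiles <- n_profiles + nrow(sig)
  }
  expect_lte(n_sig / n_profiles, 0.05)
})
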