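test_that("simulated trees are ultrametric, binary and reproducible", {
  for (n in c(3, 20)) {
    tree <- simulate_tree(n, seed = 2)
    depths <- ape::node.depth.edgelength(tree)[seq_len(n)]
    expect_lt(max(abs(depths - 1)), 1e-9)
    expect_equal(tree$Nnode, n - 1L)  # rooted binary tree
  }
  t1 <- simulate_tree(50, seed = 7)
  t2 <- simulate_tree(50, seed = 7)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  t3 <- simulate_tree(50, seed = 8)
  expect_false(identical(ape::write.tree(t1), ape::write.tree(t3)))
  expect_error(simulate_tree(2), class = "floralint_input_error")
})

test_that("null path coefficients leave traits uncorrelated with PLa", {
  truth0 <- synthetic_truth(b1 = 0, b2 = 0, b3 = 0, rho1 = 0, rho2 = 0)
  set.seed(41)
  cors <- replicate(50, {
    tree <- simulate_tree(100, seed = sample.int(1e6, 1))
    # a zeroed-out structure can push some means non-positive; only the
    # correlations matter here
    sm <- suppressWarnings(
      simulate_species_means(tree, truth0, seed = sample.int(1e6, 1)))
    c(cor(sm$PLa, sm$corolla_tube_length),
      cor(sm$PLa, sm$stigma_height),
      cor(sm$PLa, sm$upper_lip_length))
  })
  expect_true(all(abs(rowMeans(cors)) < 0.25))
})

test_that("planted residual correlation shows up in equation residuals", {
  truth <- synthetic_truth(rho1 = 0.9)
  set.seed(43)
  hits <- replicate(50, {
    tree <- simulate_tree(60, seed = sample.int(1e6, 1))
    sm <- simulate_species_means(tree, truth, seed = sample.int(1e6, 1))
    fit <- fit_psem(psem_benchmark_family()$true, sm, tree, eng = "BM")
    fit$correlated$correlation[1] > 0.6
  })
  expect_gte(mean(hits), 0.9)
})

test_that("individual flowers concentrate on species means as noise vanishes", {
  truth <- synthetic_truth(cv = 1e-6)
  tree <- simulate_tree(5, seed = 9)
  sm <- simulate_species_means(tree, truth, seed = 10)
  tab <- simulate_individuals(sm, truth, n_per_species = 30, seed = 11)
  for (i in seq_len(nrow(sm))) {
    mu <- as.numeric(sm[i, floral_traits()])
    got <- colMeans(tab[tab$species == sm$species[i], floral_traits()])
    expect_lt(max(abs(got - mu) / mu), 1e-4)
  }
  expect_error(synthetic_truth(cv = 0), class = "floralint_parameter_error")
})

test_that("stronger within-species correlation raises the integration index", {
  hi <- synthetic_truth(within_r = c(0.8, 0.8))
  lo <- synthetic_truth(within_r = c(0, 0))
  tree <- simulate_tree(3, seed = 12)
  sm <- simulate_species_means(tree, hi, seed = 13)
  set.seed(44)
  wins <- replicate(100, {
    s <- sample.int(1e6, 1)
    th <- simulate_individuals(sm[1, ], hi, n_per_species = 30, seed = s)
    tl <- simulate_individuals(sm[1, ], lo, n_per_species = 30, seed = s + 1)
    ih <- integration_index(as.matrix(th[, floral_traits()]))$percent_INT
    il <- integration_index(as.matrix(tl[, floral_traits()]))$percent_INT
    ih > il
  })
  expect_gte(mean(wins), 0.95)
})

test_that("generators are pure functions of parameters and seed", {
  truth <- synthetic_truth()
  tree <- simulate_tree(6, seed = 1)
  sm <- simulate_species_means(tree, truth, seed = 2)
  expect_identical(sm, simulate_species_means(tree, truth, seed = 2))
  t1 <- simulate_individuals(sm, truth, seed = 3)
  expect_identical(t1, simulate_individuals(sm, truth, seed = 3))
  o1 <- simulate_observations(truth, sm, seed = 4)
  expect_identical(o1, simulate_observations(truth, sm, seed = 4))
})

test_that("observed visitation recovers the matching-kernel intensity", {
  # one guild whose proboscis equals the species PLa: intensity is the
  # peak rate, and the estimated VFi should recover it
  truth <- synthetic_truth(
    guilds = data.frame(guild = "only", pl_mean = 10, pl_sd = 1),
    visit_base = 0.5)
  sm <- data.frame(species = "spX", PLa = 10,
                   t(setNames(rep(5, 8), floral_traits())))
  set.seed(45)
  est <- replicate(50, {
    o <- simulate_observations(truth, sm, n_periods = 30, seed =
                                 sample.int(1e6, 1))
    visitation_rates(o$observations, "spX")[["only"]]
  })
  expect_lt(abs(mean(est) - 0.5), 0.1)
})

test_that("equal guild proboscis lengths pin PLa to that value", {
  pli <- c(a = 8, b = 8)
  for (vf in list(c(1, 2), c(0.1, 5), c(3, 3))) {
    expect_equal(composite_proboscis_length(pli, vf)$PLa, 8)
  }
})

test_that("the lonicera-like preset honours its published scale anchors", {
  ds <- make_dataset(seed = 20)
  expect_length(ds$tree$tip.label, 11L)
  expect_equal(nrow(ds$traits), 330L)
  expect_equal(length(unique(ds$traits$species)), 11L)
  g <- ds$truth$guilds
  expect_equal(nrow(g), 5L)
  expect_equal(min(g$pl_mean), 2.45)
  expect_equal(max(g$pl_mean), 41.15)
  expect_equal(round(max(g$pl_mean) / min(g$pl_mean), 1), 16.8)
  expect_true(all(ds$traits[, floral_traits()] > 0))
  expect_error(make_dataset("unknown"), "lonicera-like",
               class = "floralint_input_error")
})
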