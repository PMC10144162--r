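test_that("covariance structures match hand-derived matrices", {
  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1);")
  expect_equal(phylo_covariance(star, "BM")$V, diag(4),
               ignore_attr = TRUE)

  tr <- hand_tree()
  V <- phylo_covariance(tr, "BM", species = c("A", "B", "C"))$V
  expect_equal(V, matrix(c(2, 1, 0, 1, 2, 0, 0, 0, 2), 3,
                         dimnames = list(c("A", "B", "C"),
                                         c("A", "B", "C"))))

  V0 <- phylo_covariance(tr, "PL", 0, species = c("A", "B", "C"))$V
  expect_equal(unname(V0), diag(c(2, 2, 2)))
  V1 <- phylo_covariance(tr, "PL", 1)$V
  expect_equal(V1, phylo_covariance(tr, "BM")$V)

  D <- ape::cophenetic.phylo(tr)
  Vou <- phylo_covariance(tr, "OU", 0.5, species = rownames(D))$V
  expect_equal(unname(diag(Vou)), rep(1, 3))
  expect_equal(Vou, exp(-0.5 * D))

  expect_error(phylo_covariance(tr, "PL", 1.5),
               class = "floralint_parameter_error")
  zero <- ape::read.tree(text = "((A:0,B:0):0,C:0);")
  expect_error(phylo_covariance(zero, "BM"), "BM",
               class = "floralint_numeric_error")
})

test_that("GLS with identity covariance reproduces OLS exactly", {
  set.seed(4)
  n <- 20
  X <- cbind(`(Intercept)` = 1, x1 = rnorm(n), x2 = rnorm(n))
  y <- 1 + 2 * X[, 2] - 0.5 * X[, 3] + rnorm(n)
  fit <- fit_gls(y, X, diag(n))
  ols <- lm(y ~ X[, 2] + X[, 3])
  expect_equal(fit$coefficients$estimate, unname(coef(ols)),
               tolerance = 1e-10)
  expect_equal(fit$coefficients$se,
               unname(summary(ols)$coefficients[, 2]), tolerance = 1e-8)
  expect_equal(fit$coefficients$p,
               unname(summary(ols)$coefficients[, 4]), tolerance = 1e-8)
})

test_that("GLS matches a brute-force dense-matrix oracle on 4 taxa", {
  set.seed(10)
  A <- matrix(rnorm(16), 4)
  V <- crossprod(A) + diag(4)
  X <- cbind(1, rnorm(4))
  y <- rnorm(4)
  fit <- fit_gls(y, X, V)
  ref <- brute_gls(y, X, V)
  expect_equal(fit$coefficients$estimate, ref$b, tolerance = 1e-10)
  expect_equal(fit$sigma2, ref$sigma2, tolerance = 1e-10)
  expect_equal(fit$logLik, ref$logLik, tolerance = 1e-8)
})

test_that("a noiseless regression is flagged degenerate with exact slope", {
  x <- 1:10
  fit <- fit_gls(2 * x, cbind(1, x), diag(10))
  expect_true(fit$degenerate)
  expect_equal(fit$coefficients$estimate[2], 2, tolerance = 1e-12)
  expect_true(is.na(fit$coefficients$p[2]))
})

test_that("rank-deficient designs raise a rank error", {
  x <- rnorm(8)
  expect_error(fit_gls(rnorm(8), cbind(1, x, 2 * x), diag(8)),
               class = "floralint_rank_error")
})

test_that("Pagel nesting identities hold on random instances", {
  set.seed(15)
  for (rep in 1:10) {
    tree <- simulate_tree(8, seed = rep)
    y <- rnorm(8)
    X <- cbind(1, rnorm(8))
    sp <- tree$tip.label
    bm <- fit_gls(y, X, phylo_covariance(tree, "BM", species = sp))
    pl1 <- fit_gls(y, X, phylo_covariance(tree, "PL", 1, species = sp))
    expect_equal(pl1$logLik, bm$logLik, tolerance = 1e-6)
    pl0 <- fit_gls(y, X, phylo_covariance(tree, "PL", 0, species = sp))
    dia <- fit_gls(y, X, diag(diag(phylo_covariance(tree, "BM",
                                                    species = sp)$V)))
    expect_equal(pl0$logLik, dia$logLik, tolerance = 1e-6)
  }
})

test_that("the profile optimum beats a lambda grid", {
  set.seed(16)
  tree <- simulate_tree(40, seed = 5)
  V <- phylo_covariance(tree, "BM")$V
  y <- as.numeric(t(chol(V)) %*% rnorm(40)) + 3
  X <- matrix(1, 40)
  fit <- fit_pgls(y, X, tree, model = "PL", species = tree$tip.label)
  for (lam in seq(0, 1, length.out = 21)) {
    g <- fit_gls(y, X, phylo_covariance(tree, "PL", lam,
                                        species = tree$tip.label))
    expect_lte(g$logLik, fit$logLik + 1e-6)
  }
})

test_that("lambda estimates track the presence and absence of signal", {
  set.seed(17)
  lam_bm <- replicate(50, {
    tree <- simulate_tree(100, seed = sample.int(1e6, 1))
    V <- phylo_covariance(tree, "BM")$V
    y <- as.numeric(t(chol(V)) %*% rnorm(100))
    fit_pgls(y, matrix(1, 100), tree, model = "PL",
             species = tree$tip.label)$parameter
  })
  expect_gte(mean(lam_bm >= 0.8), 0.9)

  set.seed(18)
  lam_perm <- replicate(50, {
    tree <- simulate_tree(100, seed = sample.int(1e6, 1))
    V <- phylo_covariance(tree, "BM")$V
    y <- sample(as.numeric(t(chol(V)) %*% rnorm(100)))
    fit_pgls(y, matrix(1, 100), tree, model = "PL",
             species = tree$tip.label)$parameter
  })
  expect_gte(mean(lam_perm <= 0.2), 0.9)
})

test_that("AIC comparison selects away from Brownian when signal is absent", {
  set.seed(19)
  non_bm <- replicate(50, {
    tree <- simulate_tree(60, seed = sample.int(1e6, 1))
    y <- rnorm(60)                      # lambda = 0 data
    X <- cbind(1, rnorm(60))
    cmp <- compare_evolutionary_models(y, X, tree,
                                       species = tree$tip.label)
    cmp$best$model != "BM"
  })
  expect_gte(mean(non_bm), 0.8)

  tree <- simulate_tree(20, seed = 1)
  cmp <- compare_evolutionary_models(rnorm(20), matrix(1, 20), tree,
                                     species = tree$tip.label)
  expect_equal(nrow(cmp$table), 3L)
  expect_equal(sum(cmp$table$selected), 1L)
  expect_error(compare_evolutionary_models(rnorm(20), matrix(1, 20),
                                           tree, models = c("BM", "BM")),
               "duplicate")
})

test_that("fixed-lambda fits agree with nlme::gls as an independent oracle", {
  tree <- simulate_tree(30, seed = 23)
  set.seed(23)
  V <- phylo_covariance(tree, "BM")$V
  dat <- data.frame(species = tree$tip.label,
                    x = as.numeric(t(chol(V)) %*% rnorm(30)))
  dat$y <- 2 + 0.8 * dat$x + as.numeric(t(chol(V)) %*% rnorm(30))
  rownames(dat) <- dat$species
  lam <- 0.6
  mine <- fit_gls(dat$y, cbind(1, x = dat$x),
                  phylo_covariance(tree, "PL", lam, species = dat$species))
  ref <- nlme::gls(y ~ x, data = dat, method = "ML",
                   correlation = ape::corPagel(lam, tree, fixed = TRUE,
                                               form = ~species))
  expect_equal(mine$coefficients$estimate, unname(coef(ref)),
               tolerance = 1e-8)
  expect_equal(mine$logLik, as.numeric(logLik(ref)), tolerance = 1e-6)
})
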