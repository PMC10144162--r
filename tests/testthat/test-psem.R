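fig_model <- function() {
  build_path_model(c("PLa -> tube", "PLa -> stigma", "stigma -> upper",
                     "tube ~~ stigma", "upper ~~ lower"))
}

test_that("path models validate structure and reject cycles and conflicts", {
  m <- fig_model()
  expect_s3_class(m, "path_model")
  expect_equal(nrow(m$edges), 3L)
  expect_equal(nrow(m$correlated), 2L)
  expect_setequal(m$exogenous, c("PLa", "lower"))
  expect_true(which(m$order == "PLa") < which(m$order == "upper"))

  expect_error(build_path_model(c("A -> B", "B -> A")),
               class = "floralint_cycle_error")
  expect_error(build_path_model(c("A -> B", "A ~~ B")),
               class = "floralint_conflict_error")
  expect_error(build_path_model(c("A -> B", "A -> B")), "duplicate")
})

test_that("path-model text files round-trip through the parser", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# the generating structure",
               "PLa -> tube", "PLa -> stigma", "stigma -> upper",
               "tube ~~ stigma", "upper ~~ lower",
               "# module: accessibility = tube"), path)
  m <- read_path_model(path)
  expect_equal(nrow(m$edges), 3L)
  expect_equal(unname(m$tags["tube"]), "accessibility")
})

test_that("basis sets follow the chain and exclusion rules", {
  chain <- build_path_model(c("A -> B", "B -> C"))
  claims <- basis_set(chain)
  expect_length(claims, 1L)
  expect_setequal(c(claims[[1]]$u, claims[[1]]$v), c("A", "C"))
  expect_equal(claims[[1]]$conditioning, "B")
  expect_equal(claims[[1]]$response, "C")  # descendant is the response

  chain_ce <- build_path_model(c("A -> B", "B -> C", "A ~~ C"))
  expect_length(basis_set(chain_ce), 0L)
})

test_that("the best-model basis set matches its textbook enumeration", {
  claims <- basis_set(fig_model())
  keys <- sapply(claims, function(cl)
    paste(sort(c(cl$u, cl$v)), collapse = "|"))
  expect_setequal(keys, c("PLa|upper", "lower|stigma", "tube|upper",
                          "lower|tube"))
  by_key <- setNames(claims, keys)
  expect_setequal(by_key[["PLa|upper"]]$conditioning, "stigma")
  expect_setequal(by_key[["tube|upper"]]$conditioning, c("PLa", "stigma"))
  expect_setequal(by_key[["lower|tube"]]$conditioning, "PLa")
  # neither ancestor: the vertex with the larger parent overlap responds
  expect_equal(by_key[["lower|tube"]]$response, "tube")
})

test_that("basis sets equal a brute-force pair scan over the whole family", {
  fams <- c(enumerate_candidate_models(), psem_benchmark_family())
  for (m in fams) {
    claims <- basis_set(m)
    got <- sapply(claims, function(cl) paste(sort(c(cl$u, cl$v)),
                                             collapse = "|"))
    want <- sapply(brute_basis_pairs(m), paste, collapse = "|")
    expect_setequal(got, want)
    for (cl in claims) {
      expect_setequal(cl$conditioning,
                      setdiff(union(m$parents[[cl$u]], m$parents[[cl$v]]),
                              c(cl$u, cl$v)))
    }
  }
})

test_that("Fisher's C and its chi-squared p behave exactly", {
  expect_equal(fisher_c(c(0.5, 0.5)), -2 * (log(0.5) + log(0.5)),
               tolerance = 1e-12)
  expect_equal(fisher_c(c(0.5, 0.5)), 2.773, tolerance = 1e-3)
  expect_equal(fisher_c_p(2.7726, 2), 0.597, tolerance = 1e-3)
  # df = 2: p = exp(-C/2) exactly
  for (C in c(0.1, 0.338, 2, 7)) {
    expect_equal(fisher_c_p(C, 1), exp(-C / 2), tolerance = 1e-12)
  }
  # independent Erlang-series oracle across df
  for (k in 1:6) for (C in c(0.4, 1.7, 6.2, 14.9)) {
    expect_equal(fisher_c_p(C, k), chisq_sf_even(C, k), tolerance = 1e-10)
  }
  expect_equal(fisher_c(c(1, 1)), 0)
  expect_equal(fisher_c_p(0, 3), 1)
  expect_error(fisher_c(c(0.5, 1.2)), class = "floralint_input_error")
})

test_that("claim tests are calibrated under the generating model", {
  set.seed(33)
  truth <- synthetic_truth()
  m <- psem_benchmark_family()$true
  p1 <- replicate(200, {
    s <- sample.int(1e6, 1)
    tree <- simulate_tree(50, seed = s)
    sm <- simulate_species_means(tree, truth, seed = s + 1)
    cl <- basis_set(m)[[1]]
    test_claim(cl, sm, tree, model = "BM")$p
  })
  expect_gte(mean(p1 < 0.05), 0.02)
  expect_lte(mean(p1 < 0.05), 0.09)
})

test_that("claims over a truly present path reject with high power", {
  set.seed(34)
  m <- build_path_model(c("x -> y1", "x -> y2"))
  hits <- replicate(50, {
    tree <- simulate_tree(100, seed = sample.int(1e6, 1))
    L <- t(chol(phylo_covariance(tree, "BM")$V))
    x <- as.numeric(L %*% rnorm(100))
    y1 <- 0.5 * x + as.numeric(L %*% rnorm(100))
    y2 <- 0.5 * x + 1.0 * y1 + as.numeric(L %*% rnorm(100))
    dat <- data.frame(species = tree$tip.label, x = x, y1 = y1, y2 = y2)
    cl <- basis_set(m)[[1]]
    test_claim(cl, dat, tree, model = "BM")$p < 0.05
  })
  expect_gte(mean(hits), 0.9)

  cl_bad <- basis_set(m)[[1]]
  expect_error(test_claim(cl_bad, data.frame(species = "a", x = 1),
                          simulate_tree(3), model = "BM"),
               class = "floralint_input_error")
})

test_that("PSEM bookkeeping ties AIC, C and K together", {
  truth <- synthetic_truth()
  tree <- simulate_tree(40, seed = 55)
  sm <- simulate_species_means(tree, truth, seed = 56)
  for (m in psem_benchmark_family()) {
    fit <- fit_psem(m, sm, tree, eng = "BM")
    endo <- setdiff(m$order, m$exogenous)
    K_ref <- sum(sapply(endo, function(v) 1 + length(m$parents[[v]]))) +
      nrow(m$correlated)
    expect_equal(fit$K, K_ref)
    expect_equal(fit$AIC - fit$C, 2 * K_ref, tolerance = 1e-12)
    expect_equal(fit$C, fisher_c(sapply(fit$claims, `[[`, "p")),
                 tolerance = 1e-12)
    expect_equal(fit$df, 2L * fit$k)
    expect_gte(fit$AIC, fit$C)
  }
  # residual correlations behind the declared pairs are reported
  fit <- fit_psem(psem_benchmark_family()$true, sm, tree, eng = "BM")
  expect_equal(nrow(fit$correlated), 2L)
  expect_gt(fit$correlated$correlation[1], 0.2)  # rho1 = 0.7 planted
})

test_that("the built-in candidate family is valid, distinct and complete", {
  fam <- enumerate_candidate_models()
  expect_gte(length(fam), 7L)
  expect_length(fam, 21L)
  keys <- sapply(fam, function(m)
    paste(sort(paste(m$edges$from, m$edges$to, sep = ">")), collapse = ";"))
  expect_equal(anyDuplicated(keys), 0L)
  for (m in fam) {
    expect_s3_class(m, "path_model")   # implies acyclic validation passed
    reach <- "PLa"
    repeat {
      nxt <- unique(c(reach, m$edges$to[m$edges$from %in% reach]))
      if (length(nxt) == length(reach)) break
      reach <- nxt
    }
    expect_true(all(c("corolla_tube_length", "stigma_height",
                      "upper_lip_length") %in% reach))
  }
  one <- enumerate_candidate_models(family = fam[2])
  expect_length(one, 1L)
  expect_error(enumerate_candidate_models(family = list()),
               class = "floralint_input_error")
})

test_that("selection filters on the d-separation screen before ranking", {
  fake <- function(C, k, K, pass) {
    structure(list(C = C, k = as.integer(k), df = 2L * as.integer(k),
                   p = fisher_c_p(C, k), K = K, AIC = C + 2 * K,
                   pass = pass),
              class = "psem_fit")
  }
  fits <- list(a = fake(30, 2, 5, FALSE), b = fake(4, 2, 9, TRUE),
               c = fake(3, 2, 12, TRUE))
  sel <- select_best_psem(fits)
  expect_equal(sel$table$model[sel$table$selected], "b")  # AIC 22 < 27
  expect_true(sel$best$pass)

  none <- select_best_psem(list(a = fake(30, 2, 5, FALSE)))
  expect_null(none$best)
  expect_match(none$note, "no admissible")
  expect_equal(nrow(none$table), 1L)
})
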