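# fixtures are built in code; nothing on disk

toy_trait_table <- function(n_species = 2, n_ind = 5, seed = 1,
                            traits = floral_traits()) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(n_species), function(i) {
    x <- matrix(abs(rnorm(n_ind * length(traits), mean = 10)), n_ind)
    colnames(x) <- traits
    data.frame(species = sprintf("sp%02d", i),
               individual = sprintf("ind%02d", seq_len(n_ind)),
               x, row.names = NULL)
  }))
}

toy_obs <- function() {
  data.frame(species = "spA",
             guild = c("beeA", "beeA", "mothB", "mothB"),
             period = c("p1", "p2", "p1", "p2"),
             visits = c(2L, 0L, 1L, 3L),
             open_flowers = c(4L, 5L, 4L, 5L))
}

toy_prob <- function() {
  data.frame(guild = c("beeA", "beeA", "mothB"),
             specimen = c("s1", "s2", "s3"),
             proboscis_length = c(2, 3, 40))
}

hand_tree <- function() ape::read.tree(text = "((A:1,B:1):1,C:2);")

# data matrix whose sample correlation matrix is exactly `R`
exact_corr_data <- function(n, R, seed = 1) {
  set.seed(seed)
  MASS::mvrnorm(n, mu = rep(10, ncol(R)), Sigma = R, empirical = TRUE)
}

# independent brute-force GLS via dense inverses, for cross-checking
brute_gls <- function(y, X, V) {
  Vi <- solve(V)
  b <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  r <- y - X %*% b
  n <- length(y)
  s2 <- as.numeric(t(r) %*% Vi %*% r) / n
  ll <- -0.5 * (n * log(2 * pi * s2) + determinant(V)$modulus + n)
  list(b = as.numeric(b), sigma2 = s2, logLik = as.numeric(ll))
}

# brute-force d-separation basis pairs: scan every vertex pair and apply
# the non-adjacent / not-correlated-error / not-both-exogenous rules
brute_basis_pairs <- function(model) {
  vs <- model$vertices
  pairs <- list()
  for (i in seq_along(vs)) for (j in seq_along(vs)) {
    if (j <= i) next
    u <- vs[i]; v <- vs[j]
    edge <- any(model$edges$from == u & model$edges$to == v) ||
      any(model$edges$from == v & model$edges$to == u)
    ce <- any((model$correlated$v1 == min(u, v)) &
                (model$correlated$v2 == max(u, v)))
    indeg_u <- sum(model$edges$to == u)
    indeg_v <- sum(model$edges$to == v)
    if (!edge && !ce && (indeg_u > 0 || indeg_v > 0)) {
      pairs <- c(pairs, list(sort(c(u, v))))
    }
  }
  pairs
}

# chi-squared survival function for even df via the Erlang closed form:
# P(X > C) = exp(-C/2) * sum_{j=0}^{k-1} (C/2)^j / j!, df = 2k
chisq_sf_even <- function(C, k) {
  j <- 0:(k - 1)
  exp(-C / 2) * sum((C / 2)^j / factorial(j))
}

equicorr_test <- function(T, r) {
  m <- matrix(r, T, T)
  diag(m) <- 1
  m
}
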