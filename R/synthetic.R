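#' Ground truth for synthetic datasets
#'
#' Bundles every parameter of the generative model: the causal path
#' coefficients of the species-mean layer (predictor -> corolla tube,
#' predictor -> stigma height, stigma height -> upper lip), the residual
#' correlations realised as correlated errors (tube~~stigma,
#' upper~~lower), the phylogenetic signal of trait residuals, the
#' within-species correlation gradient and noise level, and the
#' pollinator guild parameters.
#'
#' The upper--lower lip association is generated purely through the
#' residual correlation `rho2` (`b_lower = 0` by default), so the fitted
#' correlated-error representation is exactly right; setting `b_lower`
#' away from 0 turns it into a directed effect instead.
#'
#' @param b1,b2,b3 path coefficients predictor->tube, predictor->stigma,
#'   stigma->upper (defaults 0.207, 1.765, 0.232 mm/mm).
#' @param b_lower directed effect upper->lower (default 0; see above).
#' @param rho1,rho2 residual correlations tube~~stigma and upper~~lower
#'   (default 0.7 each).
#' @param lambda_true Pagel's lambda of the trait residuals (default 1,
#'   i.e. Brownian).
#' @param sigma_e residual standard deviations (mm) of the four causal
#'   traits.
#' @param intercepts intercepts (mm) of the four structural equations.
#' @param pla_range range (mm) spanned by the species' composite
#'   proboscis length; realised as a rescaled exponential-Brownian
#'   variable so it stays positive over a wide fold range.
#' @param within_r within-species equicorrelation bounds; a species'
#'   value interpolates linearly with its position in the PLa range, so
#'   integration increases with proboscis length.
#' @param cv within-species coefficient of variation of every trait.
#' @param guilds data.frame with columns guild, pl_mean, pl_sd (mm).
#' @param visit_base peak guild visitation intensity (visits per flower
#'   per period).
#' @param match_sd bandwidth (mm) of the Gaussian proboscis-matching
#'   kernel that sets guild visitation intensity per plant species.
#' @return a `synthetic_truth` list.
#' @export
synthetic_truth <- function(b1 = 0.207, b2 = 1.765, b3 = 0.232,
                            b_lower = 0,
                            rho1 = 0.7, rho2 = 0.7, lambda_true = 1,
                            sigma_e = c(corolla_tube_length = 0.5,
                                        stigma_height = 2.5,
                                        upper_lip_length = 1.5,
                                        lower_lip_length = 1.5),
                            intercepts = c(corolla_tube_length = 2,
                                           stigma_height = 5,
                                           upper_lip_length = 4,
                                           lower_lip_length = 7),
                            pla_range = c(2.45, 41.15),
                            within_r = c(0.3, 0.8),
                            cv = 0.08,
                            guilds = data.frame(
                              guild = c("small_carpenter_bee",
                                        "solitary_bee", "bumblebee",
                                        "butterfly", "hawk_moth"),
                              pl_mean = c(2.45, 6, 9, 15, 41.15),
                              pl_sd = 0.1 * c(2.45, 6, 9, 15, 41.15)),
                            visit_base = 0.4, match_sd = 5) {
  if (lambda_true < 0 || lambda_true > 1) {
    stop_fl("lambda_true must lie in [0, 1]",
            class = "floralint_parameter_error")
  }
  if (cv <= 0) stop_fl("cv must be > 0", class = "floralint_parameter_error")
  R_e <- diag(4)
  R_e[1, 2] <- R_e[2, 1] <- rho1
  R_e[3, 4] <- R_e[4, 3] <- rho2
  if (any(eigen(R_e, symmetric = TRUE, only.values = TRUE)$values <= 0)) {
    stop_fl("residual correlation matrix is not positive-definite",
            class = "floralint_parameter_error")
  }
  assert_finite_positive(guilds$pl_mean, "guild proboscis mean")
  structure(list(b1 = b1, b2 = b2, b3 = b3, b_lower = b_lower,
                 rho1 = rho1, rho2 = rho2, lambda_true = lambda_true,
                 sigma_e = sigma_e, intercepts = intercepts,
                 pla_range = pla_range, within_r = within_r, cv = cv,
                 guilds = guilds, visit_base = visit_base,
                 match_sd = match_sd, R_e = R_e),
            class = "synthetic_truth")
}

#' Simulate an ultrametric tree
#'
#' Pure-birth (Yule) tree with `n_tips` tips, rescaled so every
#' root-to-tip depth equals 1. Tips are labelled `sp01`, `sp02`, ...
#'
#' @param n_tips number of tips (>= 3).
#' @param seed optional integer seed; the caller's RNG stream is left
#'   untouched.
#' @return a rooted ultrametric `phylo`.
#' @export
simulate_tree <- function(n_tips, seed = NULL) {
  if (n_tips < 3L) {
    stop_fl("need at least 3 tips, got %d", n_tips,
            class = "floralint_input_error")
  }
  tree <- with_seed(seed, ape::rphylo(n_tips, birth = 1, death = 0))
  depth <- max(ape::node.depth.edgelength(tree)[seq_len(n_tips)])
  tree$edge.length <- tree$edge.length / depth
  tree$tip.label <- sprintf("sp%02d", seq_len(n_tips))
  tree
}

#' Simulate species means with a known causal structure
#'
#' The composite proboscis length of each species' assemblage is an
#' exponential-Brownian variable rescaled to span `truth$pla_range`.
#' Phylogenetic residuals of the four causal traits are multivariate
#' Brownian draws transformed by `lambda_true`, with cross-trait
#' correlations `rho1` (tube, stigma) and `rho2` (upper, lower lip), and
#' traits are assembled through the structural equations
#' tube = b1 PLa + e1, stigma = b2 PLa + e2, upper = b3 stigma + e3,
#' lower = b_lower upper + e4. Four neutral traits (throat diameter,
#' anther height, upper and lower lip width) evolve as independent
#' Brownian motion around fixed baselines and carry no predictor signal.
#'
#' @param tree rooted `phylo` with branch lengths.
#' @param truth a [synthetic_truth()].
#' @param seed optional integer seed.
#' @return data.frame, one row per tip: species, PLa and the eight trait
#'   means (mm).
#' @export
simulate_species_means <- function(tree, truth = synthetic_truth(),
                                   seed = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"))
  n <- length(tree$tip.label)
  V <- ape::vcv(tree)
  Vl <- V * truth$lambda_true
  diag(Vl) <- diag(V)
  Lbm <- t(chol(V))
  Ll <- t(chol(Vl))
  with_seed(seed, {
    z <- as.numeric(Lbm %*% rnorm(n))
    if (diff(range(z)) < 1e-12) z <- z + rnorm(n, sd = 1e-6)
    lo <- log(truth$pla_range[1L]); hi <- log(truth$pla_range[2L])
    pla <- exp(lo + (z - min(z)) / diff(range(z)) * (hi - lo))
    E <- Ll %*% matrix(rnorm(n * 4L), n, 4L) %*%
      chol(diag(truth$sigma_e) %*% truth$R_e %*% diag(truth$sigma_e))
    neutral <- Lbm %*% matrix(rnorm(n * 4L), n, 4L) %*%
      diag(c(0.4, 1.2, 0.5, 0.5))
    ic <- truth$intercepts
    tube  <- ic[[1L]] + truth$b1 * pla + E[, 1L]
    stig  <- ic[[2L]] + truth$b2 * pla + E[, 2L]
    upper <- ic[[3L]] + truth$b3 * stig + E[, 3L]
    lower <- ic[[4L]] + truth$b_lower * upper + E[, 4L]
    out <- data.frame(
      species = tree$tip.label,
      PLa = pla,
      corolla_tube_length = tube,
      throat_diameter = 4 + neutral[, 1L],
      anther_height = 8 + neutral[, 2L],
      stigma_height = stig,
      upper_lip_length = upper,
      upper_lip_width = 3.5 + neutral[, 3L],
      lower_lip_length = lower,
      lower_lip_width = 3.5 + neutral[, 4L],
      row.names = NULL
    )
    if (any(out[, -1L] <= 0)) {
      warning("some simulated species means are non-positive; consider smaller noise")
    }
    out
  })
}

#' Simulate individual flowers
#'
#' Draws `n_per_species` multivariate-normal flowers per species around
#' the species' trait means, with per-trait standard deviation `cv` times
#' the mean and an equicorrelation matrix whose strength interpolates
#' over `truth$within_r` with the species' position in the PLa range
#' (more integrated flowers on longer-proboscis assemblages). Rows with
#' any non-positive value are redrawn; the redraw count is attached as
#' attribute `n_redrawn`.
#'
#' @param species_means output of [simulate_species_means()].
#' @param truth a [synthetic_truth()].
#' @param n_per_species flowers per species (default 30).
#' @param seed optional integer seed.
#' @return a trait table: species, individual and the eight trait
#'   columns.
#' @export
simulate_individuals <- function(species_means, truth = synthetic_truth(),
                                 n_per_species = 30, seed = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"))
  traits <- setdiff(names(species_means), c("species", "PLa"))
  pla <- species_means$PLa
  rel <- if (diff(range(pla)) > 0) {
    (pla - min(pla)) / diff(range(pla))
  } else rep(0.5, length(pla))
  r_s <- truth$within_r[1L] + rel * diff(truth$within_r)
  redrawn <- 0L
  with_seed(seed, {
    blocks <- lapply(seq_len(nrow(species_means)), function(i) {
      mu <- as.numeric(species_means[i, traits])
      if (any(mu <= 0)) {
        stop_fl("species '%s' has a non-positive mean trait",
                species_means$species[i],
                class = "floralint_parameter_error")
      }
      sdv <- truth$cv * mu
      Sigma <- diag(sdv) %*% equicorr(length(mu), r_s[i]) %*% diag(sdv)
      x <- rmvnorm_chol(n_per_species, mu, Sigma)
      bad <- which(apply(x, 1L, function(r) any(r <= 0)))
      while (length(bad)) {
        redrawn <<- redrawn + length(bad)
        x[bad, ] <- rmvnorm_chol(length(bad), mu, Sigma)
        bad <- bad[apply(x[bad, , drop = FALSE], 1L,
                         function(r) any(r <= 0))]
      }
      colnames(x) <- traits
      data.frame(species = species_means$species[i],
                 individual = sprintf("%s_%02d", species_means$species[i],
                                      seq_len(n_per_species)),
                 x, row.names = NULL)
    })
    structure(do.call(rbind, blocks), n_redrawn = redrawn)
  })
}

#' Simulate pollinator observations and proboscis specimens
#'
#' Visitation intensity of guild g on species s follows a Gaussian
#' proboscis-matching kernel,
#' \eqn{\mu_{sg} = \mathrm{visit\_base} \cdot
#'   \exp(-(PLa_s - PL_g)^2 / (2\,\mathrm{match\_sd}^2))},
#' so guilds whose proboscis matches the assemblage value visit most.
#' Every species is watched for `n_periods` periods; the number of open
#' flowers per period is uniform on 5..15 and visit counts are Poisson
#' with mean intensity times flowers. Twenty proboscis specimens per
#' guild are drawn from a positive-truncated normal.
#'
#' @param truth a [synthetic_truth()].
#' @param species_means output of [simulate_species_means()].
#' @param n_periods observation periods per species (default 30).
#' @param n_specimens proboscis specimens per guild (default 20).
#' @param seed optional integer seed.
#' @return list with `observations` (species, guild, period, visits,
#'   open_flowers) and `proboscis` (guild, specimen, proboscis_length).
#' @export
simulate_observations <- function(truth, species_means, n_periods = 30,
                                  n_specimens = 20, seed = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"))
  g <- truth$guilds
  with_seed(seed, {
    obs <- do.call(rbind, lapply(seq_len(nrow(species_means)), function(i) {
      s <- species_means$species[i]
      intensity <- truth$visit_base *
        exp(-(species_means$PLa[i] - g$pl_mean)^2 / (2 * truth$match_sd^2))
      if (all(intensity <= 0)) {
        warning(sprintf("species '%s' has zero visitation intensity", s))
      }
      flowers <- sample(5:15, n_periods, replace = TRUE)
      do.call(rbind, lapply(seq_len(n_periods), function(p) {
        data.frame(species = s, guild = g$guild,
                   period = sprintf("%s_p%02d", s, p),
                   visits = rpois(nrow(g), intensity * flowers[p]),
                   open_flowers = flowers[p], row.names = NULL)
      }))
    }))
    prob <- do.call(rbind, lapply(seq_len(nrow(g)), function(j) {
      x <- rnorm(n_specimens, g$pl_mean[j], g$pl_sd[j])
      while (any(x <= 0)) {
        x[x <= 0] <- rnorm(sum(x <= 0), g$pl_mean[j], g$pl_sd[j])
      }
      data.frame(guild = g$guild[j],
                 specimen = sprintf("%s_%02d", g$guild[j],
                                    seq_len(n_specimens)),
                 proboscis_length = x, row.names = NULL)
    }))
    list(observations = obs, proboscis = prob)
  })
}

#' Generate a complete synthetic dataset
#'
#' The `"lonicera-like"` preset emulates the honeysuckle study system:
#' 11 species on an ultrametric tree, 8 floral traits with 30 flowers
#' per species, and 5 pollinator guilds whose mean proboscis lengths
#' span 2.45--41.15 mm, with the causal structure of
#' [simulate_species_means()] and full ground truth attached.
#'
#' @param preset preset name; currently `"lonicera-like"`.
#' @param seed integer seed driving every stage.
#' @param truth optionally override the preset's [synthetic_truth()].
#' @return list with `tree`, `species_means`, `traits`, `observations`,
#'   `proboscis` and `truth`.
#' @export
make_dataset <- function(preset = "lonicera-like", seed = 1,
                         truth = NULL) {
  presets <- c("lonicera-like")
  if (!preset %in% presets) {
    stop_fl("unknown preset '%s'; available: %s", preset,
            paste(presets, collapse = ", "),
            class = "floralint_input_error")
  }
  truth <- truth %||% synthetic_truth()
  tree <- simulate_tree(11, seed = seed)
  means <- simulate_species_means(tree, truth, seed = seed + 1)
  traits <- simulate_individuals(means, truth, n_per_species = 30,
                                 seed = seed + 2)
  op <- simulate_observations(truth, means, n_periods = 30,
                              seed = seed + 3)
  list(tree = tree, species_means = means, traits = traits,
       observations = op$observations, proboscis = op$proboscis,
       truth = truth)
}
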