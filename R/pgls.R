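#' Phylogenetic covariance structures
#'
#' Build the tip-to-tip covariance (or correlation) matrix implied by an
#' evolutionary model on a rooted tree with branch lengths.
#'
#' Three structures are supported:
#' \describe{
#'   \item{BM}{Brownian motion: \eqn{C_{ij}} is the shared path length from
#'     the root to the most recent common ancestor of tips i and j; the
#'     diagonal holds root-to-tip depths.}
#'   \item{PL}{Pagel's lambda: the BM matrix with every off-diagonal entry
#'     multiplied by \eqn{\lambda \in [0, 1]}. \eqn{\lambda = 1} is BM,
#'     \eqn{\lambda = 0} removes all phylogenetic covariance.}
#'   \item{OU}{stationary Ornstein--Uhlenbeck (Martins--Hansen) correlation
#'     \eqn{\exp(-\alpha d_{ij})} with \eqn{d_{ij}} the patristic distance;
#'     the diagonal is 1.}
#' }
#'
#' @param tree a rooted `phylo` tree with branch lengths.
#' @param model one of `"BM"`, `"PL"`, `"OU"`.
#' @param parameter \eqn{\lambda} for `"PL"` (in \[0, 1\]) or \eqn{\alpha}
#'   (> 0) for `"OU"`; must be omitted for `"BM"`.
#' @param species tip labels fixing the row/column order; defaults to the
#'   tree's tip order. All must be tips of `tree`.
#' @return an object of class `phylo_vcv`: a list with elements `model`,
#'   `parameter`, `V` (the matrix, dimnames = species) and `species`.
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
#' phylo_covariance(tr, "BM")$V
#' @export
phylo_covariance <- function(tree, model = c("BM", "PL", "OU"),
                             parameter = NULL, species = NULL) {
  model <- match.arg(model)
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) {
    stop_fl("tree has no branch lengths; a %s covariance is undefined",
            model, class = "floralint_tree_error")
  }
  species <- species %||% tree$tip.label
  missing <- setdiff(species, tree$tip.label)
  if (length(missing)) {
    stop_fl("species not in tree: %s", paste(missing, collapse = ", "),
            class = "floralint_tree_error")
  }
  V <- switch(model,
    BM = ape::vcv(tree)[species, species, drop = FALSE],
    PL = {
      lambda <- parameter
      if (is.null(lambda) || !is.finite(lambda) || lambda < 0 || lambda > 1) {
        stop_fl("Pagel's lambda must lie in [0, 1]",
                class = "floralint_parameter_error")
      }
      v <- ape::vcv(tree)[species, species, drop = FALSE]
      d <- diag(v)
      v <- v * lambda
      diag(v) <- d
      v
    },
    OU = {
      alpha <- parameter
      if (is.null(alpha) || !is.finite(alpha) || alpha <= 0) {
        stop_fl("OU alpha must be > 0", class = "floralint_parameter_error")
      }
      D <- ape::cophenetic.phylo(tree)[species, species, drop = FALSE]
      exp(-alpha * D)
    }
  )
  ok <- tryCatch({ chol(V); TRUE }, error = function(e) FALSE)
  if (!ok) {
    stop_fl("%s covariance is not positive-definite for this tree", model,
            class = "floralint_numeric_error")
  }
  structure(list(model = model, parameter = parameter, V = V,
                 species = species),
            class = "phylo_vcv")
}

#' @export
print.phylo_vcv <- function(x, ...) {
  cat(sprintf("phylogenetic covariance: model %s%s, %d tips\n", x$model,
              if (is.null(x$parameter)) "" else
                sprintf(" (parameter = %.4g)", x$parameter),
              length(x$species)))
  invisible(x)
}

#' Generalized least squares with a fixed covariance
#'
#' Fits \eqn{y = X b + e}, \eqn{e \sim N(0, \sigma^2 V)} by maximum
#' likelihood via the Cholesky factor of `V`. \eqn{\hat b =
#' (X'V^{-1}X)^{-1} X'V^{-1} y}; \eqn{\hat\sigma^2_{ML} = r'V^{-1}r/n};
#' \eqn{\log L = -\tfrac12 [n \log(2\pi\hat\sigma^2) + \log|V| + n]}.
#' Standard errors use the unbiased rescale \eqn{n/(n-p)} of the ML
#' variance; t tests have \eqn{n - p} degrees of freedom.
#'
#' @param y numeric response vector.
#' @param X design matrix (include the intercept column yourself, or use
#'   [fit_pgls()] / [pgls()] which build it).
#' @param V an n-by-n positive-definite matrix or a [phylo_covariance()]
#'   object.
#' @param model_tag label stored in the result (e.g. the evolutionary
#'   model that produced `V`).
#' @param parameter structural parameter stored alongside `model_tag`.
#' @param n_structural number of estimated structural parameters counted
#'   in the AIC (0 when `V` is fixed).
#' @return a `gls_fit`: list with `coefficients` (data.frame: estimate,
#'   se, t, p), `sigma2` (ML), `logLik`, `AIC`, `n`, `df.residual`,
#'   `model`, `parameter`, `fitted`, `residuals`, `degenerate` (TRUE when
#'   \eqn{\hat\sigma^2} is numerically zero).
#' @export
fit_gls <- function(y, X, V, model_tag = "fixed", parameter = NULL,
                    n_structural = 0L) {
  if (inherits(V, "phylo_vcv")) {
    model_tag <- V$model
    parameter <- V$parameter
    V <- V$V
  }
  y <- as.numeric(y)
  X <- as.matrix(X)
  n <- length(y)
  p <- ncol(X)
  if (nrow(X) != n || nrow(V) != n || ncol(V) != n) {
    stop_fl("dimension mismatch: y (%d), X (%d x %d), V (%d x %d)",
            n, nrow(X), p, nrow(V), ncol(V),
            class = "floralint_dimension_error")
  }
  U <- chol(V)                      # V = U'U
  ys <- backsolve(U, y, transpose = TRUE)
  Xs <- backsolve(U, X, transpose = TRUE)
  qrX <- qr(Xs)
  if (qrX$rank < p) {
    stop_fl("design matrix is rank-deficient (rank %d < %d columns)",
            qrX$rank, p, class = "floralint_rank_error")
  }
  b <- qr.coef(qrX, ys)
  r <- ys - Xs %*% b
  rss <- sum(r^2)
  sigma2 <- rss / n
  logdetV <- 2 * sum(log(diag(U)))
  degenerate <- sigma2 < 1e-12 * max(1, mean(y^2))
  logLik <- if (degenerate) Inf else
    -0.5 * (n * log(2 * pi * sigma2) + logdetV + n)
  XtX_inv <- chol2inv(qr.R(qrX))
  if (degenerate) {
    se <- tstat <- pval <- rep(NA_real_, p)
  } else {
    se <- sqrt(diag(XtX_inv) * sigma2 * n / (n - p))
    tstat <- b / se
    pval <- 2 * pt(-abs(tstat), df = n - p)
  }
  npar <- p + 1L + as.integer(n_structural)
  coef_tab <- data.frame(estimate = as.numeric(b), se = se, t = tstat,
                         p = pval,
                         row.names = colnames(X) %||% paste0("b", seq_len(p)))
  structure(list(coefficients = coef_tab, sigma2 = sigma2,
                 logLik = logLik,
                 AIC = if (is.finite(logLik)) -2 * logLik + 2 * npar else -Inf,
                 n = n, df.residual = n - p,
                 model = model_tag, parameter = parameter,
                 boundary = FALSE,
                 fitted = as.numeric(X %*% b),
                 residuals = as.numeric(y - X %*% b),
                 degenerate = degenerate),
            class = "gls_fit")
}

#' @export
print.gls_fit <- function(x, ...) {
  cat(sprintf("GLS fit (model %s%s), n = %d, logLik = %.4f, AIC = %.4f\n",
              x$model,
              if (is.null(x$parameter)) "" else
                sprintf(", parameter = %.4g", x$parameter),
              x$n, x$logLik, x$AIC))
  print(format(x$coefficients, digits = 4))
  if (x$degenerate) cat("note: residual variance is numerically zero\n")
  invisible(x)
}

#' Phylogenetic generalized least squares
#'
#' PGLS of `y` on `X` over the tips of `tree` under a Brownian-motion,
#' Pagel's-lambda or Ornstein--Uhlenbeck covariance. For `"PL"` and
#' `"OU"` the structural parameter is estimated by maximizing the profile
#' log-likelihood with a bounded scalar search (\eqn{\lambda \in [0,1]};
#' \eqn{\log\alpha \in [-10, 10]}) to tolerance 1e-8; its one parameter is
#' counted in the AIC. Boundary optima are flagged, not errors.
#'
#' @inheritParams fit_gls
#' @param tree rooted `phylo` with branch lengths.
#' @param model `"BM"`, `"PL"` or `"OU"`.
#' @param species tip labels giving the order of `y` rows (defaults to
#'   `names(y)`, then the tree's tip order).
#' @return a `gls_fit` with `parameter` set to \eqn{\hat\lambda} or
#'   \eqn{\hat\alpha} and `boundary = TRUE` when the optimum lies on the
#'   search boundary.
#' @seealso [compare_evolutionary_models()]
#' @export
fit_pgls <- function(y, X, tree, model = c("BM", "PL", "OU"),
                     species = NULL) {
  model <- match.arg(model)
  species <- species %||% names(y) %||% tree$tip.label
  if (length(species) != length(y)) {
    stop_fl("species labels (%d) do not match y (%d)",
            length(species), length(y), class = "floralint_dimension_error")
  }
  if (model == "BM") {
    return(fit_gls(y, X, phylo_covariance(tree, "BM", species = species)))
  }
  if (length(y) < 4L) {
    stop_fl("estimating a structural parameter needs >= 4 species",
            class = "floralint_dimension_error")
  }
  # precompute the ingredients once; the profile just rescales them
  if (model == "PL") {
    B <- ape::vcv(tree)[species, species, drop = FALSE]
    make_V <- function(par) {           # par = lambda
      v <- B * par
      diag(v) <- diag(B)
      v
    }
    lower <- 0; upper <- 1
    to_param <- identity
  } else {
    D <- ape::cophenetic.phylo(tree)[species, species, drop = FALSE]
    make_V <- function(par) exp(-exp(par) * D)   # par = log(alpha)
    lower <- -10; upper <- 10
    to_param <- exp
  }
  prof <- function(par) {
    f <- tryCatch(fit_gls(y, X, make_V(par)), error = function(e) NULL)
    if (is.null(f)) -Inf else f$logLik
  }
  opt <- optimize(prof, c(lower, upper), maximum = TRUE, tol = 1e-8)
  par_hat <- opt$maximum
  # optimize() never evaluates the exact endpoints; take a boundary value
  # if it beats the interior optimum.
  for (bnd in c(lower, upper)) {
    if (prof(bnd) > opt$objective + 1e-9) par_hat <- bnd
  }
  fit <- fit_gls(y, X, make_V(par_hat), model_tag = model,
                 parameter = to_param(par_hat), n_structural = 1L)
  fit$boundary <- min(par_hat - lower, upper - par_hat) < 1e-6
  fit
}

#' Formula interface to PGLS
#'
#' Convenience wrapper: builds the response and design matrix from a
#' formula and a species-level data frame (one row per tip, species given
#' by the `species` column or row names), then calls [fit_pgls()].
#'
#' @param formula model formula, e.g. `percent_INT ~ PLa`.
#' @param data data frame with one row per species.
#' @param tree rooted `phylo`.
#' @param model evolutionary model tag, see [fit_pgls()].
#' @export
pgls <- function(formula, data, tree, model = c("BM", "PL", "OU")) {
  model <- match.arg(model)
  species <- data$species %||% rownames(data)
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  fit_pgls(y, X, tree, model = model, species = as.character(species))
}

#' Compare evolutionary models by AIC
#'
#' Fits the same regression under several phylogenetic covariance models
#' and returns the minimum-AIC fit together with the comparison table.
#' Ties (difference < 1e-6) are broken by simplicity: BM, then PL, then
#' OU. A model that fails to fit is kept in the table with `failed =
#' TRUE`; if all fail, an error is raised.
#'
#' @inheritParams fit_pgls
#' @param models character vector of distinct model tags.
#' @return list with `best` (a `gls_fit`), `table` (data.frame: model,
#'   parameter, logLik, AIC, dAIC, selected, failed) and `fits`.
#' @export
compare_evolutionary_models <- function(y, X, tree,
                                        models = c("BM", "PL", "OU"),
                                        species = NULL) {
  if (anyDuplicated(models)) {
    stop_fl("duplicate model in model list: %s",
            paste(unique(models[duplicated(models)]), collapse = ", "),
            class = "floralint_input_error")
  }
  simplicity <- c(BM = 1L, PL = 2L, OU = 3L)
  models <- models[order(simplicity[models])]
  fits <- lapply(models, function(m) {
    tryCatch(fit_pgls(y, X, tree, model = m, species = species),
             error = function(e) NULL)
  })
  names(fits) <- models
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) {
    stop_fl("all evolutionary models failed to fit",
            class = "floralint_fit_error")
  }
  aic <- vapply(fits, function(f) if (is.null(f)) NA_real_ else f$AIC,
                numeric(1))
  best_aic <- min(aic[ok])
  # within-tolerance ties go to the simplest model (list is ordered)
  best_idx <- which(ok & aic <= best_aic + 1e-6)[1L]
  tab <- data.frame(
    model = models,
    parameter = vapply(fits, function(f)
      if (is.null(f) || is.null(f$parameter)) NA_real_ else f$parameter,
      numeric(1)),
    logLik = vapply(fits, function(f)
      if (is.null(f)) NA_real_ else f$logLik, numeric(1)),
    AIC = aic,
    dAIC = aic - best_aic,
    selected = seq_along(models) == best_idx,
    failed = !ok,
    row.names = NULL
  )
  list(best = fits[[best_idx]], table = tab, fits = fits)
}
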