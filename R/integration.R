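#' Trait correlation matrix
#'
#' Pearson (default) or Spearman correlation matrix of an individuals-by-
#' traits measurement matrix. Rows with missing values must be dropped
#' upstream; a constant column is a hard error because its correlations
#' are undefined.
#'
#' @param values numeric matrix or data frame, N individuals x T traits,
#'   N >= 3.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return T x T correlation matrix (symmetric, unit diagonal).
#' @export
correlation_matrix <- function(values, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  values <- as.matrix(values)
  if (!is.numeric(values)) {
    stop_fl("trait values must be numeric", class = "floralint_input_error")
  }
  if (anyNA(values) || any(!is.finite(values))) {
    stop_fl("trait values contain missing or non-finite cells",
            class = "floralint_input_error")
  }
  if (nrow(values) < 3L) {
    stop_fl("need at least 3 individuals, got %d", nrow(values),
            class = "floralint_input_error")
  }
  sds <- apply(values, 2L, sd)
  if (any(sds == 0)) {
    nm <- colnames(values) %||% as.character(seq_len(ncol(values)))
    stop_fl("degenerate trait (constant column): %s",
            paste(nm[sds == 0], collapse = ", "),
            class = "floralint_degenerate_trait_error")
  }
  cor(values, method = method)
}

#' Phenotypic integration index (eigenvalue variance)
#'
#' The index of phenotypic integration of a species is the variance of
#' the eigenvalues \eqn{\lambda_i} of the Pearson correlation matrix of
#' its trait measurements. With all traits perfectly correlated the
#' eigenvalues are \eqn{\{T, 0, \dots, 0\}} and the sample variance
#' (divisor T-1) attains the maximum T, the number of traits; with
#' independent traits all eigenvalues are 1 and the variance is 0. The
#' small-sample correction subtracts \eqn{(T-1)/N}; the percent scale is
#' \eqn{100 \cdot \mathrm{INT}/T}, i.e. percent of the attainable
#' maximum.
#'
#' The sample-variance convention (divisor T-1) is the default because it
#' is the only one under which the maximum equals the number of traits.
#' Note that under this convention the raw index of truly independent
#' normal traits has expectation \eqn{T/(N-1)}, slightly above the
#' classical correction \eqn{(T-1)/N}, so the corrected index retains a
#' small positive bias of \eqn{T/(N-1) - (T-1)/N}; `divisor =
#' "population"` (divisor T, maximum T-1) removes most of that bias at
#' the cost of the maximum-equals-T property.
#'
#' @inheritParams correlation_matrix
#' @param species_id optional label stored in the result.
#' @param apply_correction subtract \eqn{(T-1)/N}? Default TRUE.
#' @param percent_scale also express the corrected index as percent of
#'   the maximum T? Default TRUE.
#' @param divisor `"sample"` (T-1, default) or `"population"` (T) in the
#'   eigenvalue variance.
#' @return an `integration_result`: list with `species_id`, `T`, `N`,
#'   `eigenvalues`, `raw_variance`, `corrected_INT`, `percent_INT`,
#'   `negative` (TRUE when the corrected index is below zero; it is
#'   reported as-is, not floored), plus CI fields filled by
#'   [bootstrap_integration()].
#' @examples
#' x <- matrix(rnorm(30), 10, 3)
#' x <- cbind(x, x)  # duplicated block -> strong integration
#' integration_index(x)
#' @export
integration_index <- function(values, species_id = NA_character_,
                              apply_correction = TRUE, percent_scale = TRUE,
                              method = c("pearson", "spearman"),
                              divisor = c("sample", "population")) {
  divisor <- match.arg(divisor)
  values <- as.matrix(values)
  T <- ncol(values)
  N <- nrow(values)
  if (T < 2L) {
    stop_fl("integration needs at least 2 traits, got %d", T,
            class = "floralint_input_error")
  }
  C <- correlation_matrix(values, method = method)
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  raw <- if (divisor == "sample") var(ev) else
    sum((ev - mean(ev))^2) / T
  corrected <- if (apply_correction) raw - (T - 1) / N else raw
  pct <- if (percent_scale) 100 * corrected / T else NA_real_
  structure(list(species_id = species_id, T = T, N = N,
                 eigenvalues = ev, raw_variance = raw,
                 corrected_INT = corrected, percent_INT = pct,
                 negative = corrected < 0,
                 ci_low = NA_real_, ci_high = NA_real_, n_boot = 0L),
            class = "integration_result")
}

#' @export
print.integration_result <- function(x, ...) {
  cat(sprintf(
    "integration index%s: T = %d traits, N = %d individuals\n",
    if (is.na(x$species_id)) "" else sprintf(" [%s]", x$species_id),
    x$T, x$N))
  cat(sprintf("  raw eigenvalue variance %.4f, corrected %.4f, percent %.3f%%\n",
              x$raw_variance, x$corrected_INT, x$percent_INT))
  if (x$n_boot > 0) {
    cat(sprintf("  bootstrap 95%% CI [%.3f, %.3f] (%d replicates)\n",
                x$ci_low, x$ci_high, x$n_boot))
  }
  invisible(x)
}

#' Percentile bootstrap for the integration index
#'
#' Resamples the N individuals with replacement `n_boot` times and takes
#' percentile bounds on the percent-scaled corrected index. Resamples in
#' which a trait becomes constant (so the correlation matrix is
#' undefined) are redrawn; the redraw count is stored in the result.
#'
#' @inheritParams integration_index
#' @param n_boot number of bootstrap replicates (default 5000).
#' @param seed optional integer; the caller's RNG stream is left
#'   untouched.
#' @param conf confidence level of the percentile interval (default
#'   0.95).
#' @return an `integration_result` with `ci_low`, `ci_high`, `n_boot`,
#'   `boot_percent` (the replicate values) and `n_redrawn` filled in.
#' @export
bootstrap_integration <- function(values, n_boot = 5000, seed = NULL,
                                  conf = 0.95, species_id = NA_character_,
                                  method = c("pearson", "spearman"),
                                  divisor = c("sample", "population")) {
  if (!is.numeric(n_boot) || n_boot < 1) {
    stop_fl("n_boot must be >= 1", class = "floralint_input_error")
  }
  values <- as.matrix(values)
  res <- integration_index(values, species_id = species_id,
                           method = method, divisor = divisor)
  N <- nrow(values)
  boot <- numeric(n_boot)
  redrawn <- 0L
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      repeat {
        idx <- sample.int(N, N, replace = TRUE)
        vb <- values[idx, , drop = FALSE]
        if (all(apply(vb, 2L, sd) > 0)) break
        redrawn <- redrawn + 1L
        if (redrawn > 100L * n_boot) {
          stop_fl("bootstrap cannot find non-degenerate resamples",
                  class = "floralint_degenerate_trait_error")
        }
      }
      boot[b] <- integration_index(vb, method = method,
                                   divisor = divisor)$percent_INT
    }
  })
  alpha <- (1 - conf) / 2
  ci <- quantile(boot, c(alpha, 1 - alpha), names = FALSE)
  res$ci_low <- ci[1L]
  res$ci_high <- ci[2L]
  res$n_boot <- as.integer(n_boot)
  res$boot_percent <- boot
  res$n_redrawn <- redrawn
  res
}

#' Per-species integration table
#'
#' Runs [bootstrap_integration()] for every species of a trait table and
#' returns one row per species. Two species are scored as differing in
#' integration when their percentile CIs do not overlap.
#'
#' @param table a trait table (see [read_trait_table()]).
#' @param traits trait columns to use; defaults to all trait columns.
#' @param n_boot,seed,conf,divisor passed to [bootstrap_integration()].
#' @return data.frame with columns species, T, N, raw_variance,
#'   corrected_INT, percent_INT, negative, ci_low, ci_high, n_boot; the
#'   full `integration_result` objects are attached as attribute
#'   `"results"`.
#' @export
species_integration <- function(table, traits = NULL, n_boot = 5000,
                                seed = NULL, conf = 0.95,
                                divisor = c("sample", "population")) {
  traits <- traits %||% trait_columns(table)
  sp <- unique(table$species)
  results <- lapply(seq_along(sp), function(i) {
    vals <- as.matrix(table[table$species == sp[i], traits, drop = FALSE])
    bootstrap_integration(vals, n_boot = n_boot,
                          seed = if (is.null(seed)) NULL else seed + i,
                          conf = conf, species_id = sp[i], divisor = divisor)
  })
  out <- data.frame(
    species = sp,
    T = vapply(results, `[[`, integer(1), "T"),
    N = vapply(results, `[[`, integer(1), "N"),
    raw_variance = vapply(results, `[[`, numeric(1), "raw_variance"),
    corrected_INT = vapply(results, `[[`, numeric(1), "corrected_INT"),
    percent_INT = vapply(results, `[[`, numeric(1), "percent_INT"),
    negative = vapply(results, `[[`, logical(1), "negative"),
    ci_low = vapply(results, `[[`, numeric(1), "ci_low"),
    ci_high = vapply(results, `[[`, numeric(1), "ci_high"),
    n_boot = vapply(results, `[[`, integer(1), "n_boot"),
    row.names = NULL
  )
  attr(out, "results") <- results
  out
}
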