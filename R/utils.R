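# internal helpers shared across modules

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` under a fixed seed without disturbing the caller's RNG
# stream; seed = NULL uses the current stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' @noRd
stop_fl <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c(class, "floralint_error")))
}

#' @noRd
assert_finite_positive <- function(x, what) {
  bad <- !is.finite(x) | x <= 0
  if (any(bad)) {
    stop_fl("%s must be finite and > 0 (%d offending value(s), first at row %d)",
            what, sum(bad), which(bad)[1L], class = "floralint_validation_error")
  }
  invisible(x)
}

# T x T equicorrelation matrix; used by generators and tests.
#' @noRd
equicorr <- function(T, r) {
  m <- matrix(r, T, T)
  diag(m) <- 1
  m
}

# Draw n rows from MVN(mu, Sigma) via the Cholesky factor.
#' @noRd
rmvnorm_chol <- function(n, mu, Sigma) {
  L <- chol(Sigma)
  z <- matrix(rnorm(n * length(mu)), n, length(mu))
  sweep(z %*% L, 2L, mu, "+")
}

# Minimal line logger: appends "LEVEL message" strings to a collector
# environment created by new_log(); pipeline writes them to the log file.
#' @noRd
new_log <- function(verbose = getOption("floralint.verbose", FALSE)) {
  env <- new.env(parent = emptyenv())
  env$lines <- character()
  env$verbose <- isTRUE(verbose)
  env
}

#' @noRd
log_line <- function(log, level, fmt, ...) {
  if (is.null(log)) return(invisible(NULL))
  msg <- sprintf("%s %s", level, sprintf(fmt, ...))
  log$lines <- c(log$lines, msg)
  if (isTRUE(log$verbose)) message(msg)
  invisible(msg)
}
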