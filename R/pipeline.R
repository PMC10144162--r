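#' Assemble a pipeline configuration
#'
#' Either the three input paths (`trait_path`, `tree_path`, `obs_path` +
#' `prob_path`) or an in-memory `dataset` from [make_dataset()] must be
#' supplied. A YAML file with the same field names can be loaded with
#' [read_run_config()].
#'
#' @param trait_path,tree_path,obs_path,prob_path input file paths.
#' @param dataset in-memory dataset (overrides the paths).
#' @param out_dir output directory for reports and the log.
#' @param traits trait columns used throughout.
#' @param models evolutionary models fitted in the PGLS screen.
#' @param n_boot bootstrap replicates for the integration CI (default
#'   5000).
#' @param seed integer seed for every stochastic step.
#' @param stages subset of `c("integrate", "pla", "pgls", "psem")`;
#'   prerequisite computations run as needed but only requested stages
#'   are reported.
#' @param psem_family `"builtin"` or a list of `path_model`s.
#' @param aggregation visitation-rate aggregation, see
#'   [visitation_rates()].
#' @param alpha screening and d-separation level (default 0.05).
#' @param eng evolutionary-model choice for PSEM equations (default
#'   `"best"`).
#' @return a `run_config` list.
#' @export
make_run_config <- function(trait_path = NULL, tree_path = NULL,
                            obs_path = NULL, prob_path = NULL,
                            dataset = NULL, out_dir = tempfile("floralint_"),
                            traits = floral_traits(),
                            models = c("BM", "PL", "OU"),
                            n_boot = 5000, seed = 1,
                            stages = c("integrate", "pla", "pgls", "psem"),
                            psem_family = "builtin",
                            aggregation = "mean_rate", alpha = 0.05,
                            eng = "best") {
  if (n_boot < 1) stop_fl("n_boot must be >= 1",
                          class = "floralint_input_error")
  if (length(seed) != 1L || !is.finite(seed) || seed != round(seed)) {
    stop_fl("seed must be a single integer", class = "floralint_input_error")
  }
  bad <- setdiff(stages, c("integrate", "pla", "pgls", "psem"))
  if (length(bad)) {
    stop_fl("unknown stage(s): %s", paste(bad, collapse = ", "),
            class = "floralint_input_error")
  }
  structure(list(trait_path = trait_path, tree_path = tree_path,
                 obs_path = obs_path, prob_path = prob_path,
                 dataset = dataset, out_dir = out_dir, traits = traits,
                 models = models, n_boot = n_boot,
                 seed = as.integer(seed), stages = stages,
                 psem_family = psem_family, aggregation = aggregation,
                 alpha = alpha, eng = eng),
            class = "run_config")
}

#' @rdname make_run_config
#' @param path YAML configuration file.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(make_run_config, cfg)
}

#' Run the full analysis pipeline
#'
#' Orchestrates, on one dataset: per-species integration with bootstrap
#' CI; per-species composite proboscis length PLa; the PGLS screen of
#' integration against each trait and PLa under all evolutionary models
#' (with a non-phylogenetic OLS fit reported alongside); and piecewise
#' SEM over the candidate family restricted to the screened traits, with
#' Fisher's-C based selection. Writes machine-readable TSV tables, a
#' consolidated JSON report and an INFO-level log of every screening
#' decision into `config$out_dir`. Identical configuration and seed give
#' byte-identical JSON reports.
#'
#' @param config a [make_run_config()].
#' @return (invisibly) list with the per-stage results, the report list
#'   and the paths written.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  log <- new_log()
  set.seed(config$seed)
  # ---- load inputs -------------------------------------------------
  if (!is.null(config$dataset)) {
    ds <- config$dataset
    traits_tab <- validate_trait_table(ds$traits, traits = config$traits,
                                       where = "dataset$traits")
    tree <- ds$tree
    obs <- ds$observations
    prob <- ds$proboscis
    log_line(log, "INFO", "using in-memory dataset (%d trait rows)",
             nrow(traits_tab))
  } else {
    for (p in c(config$trait_path, config$tree_path, config$obs_path,
                config$prob_path)) {
      if (is.null(p) || !file.exists(p)) {
        stop_fl("pipeline input missing or unreadable: %s",
                p %||% "<unset path>", class = "floralint_input_error")
      }
    }
    traits_tab <- read_trait_table(config$trait_path,
                                   traits = config$traits)
    tree <- read_phylo_tree(config$tree_path, log = log)
    op <- read_observations(config$obs_path, config$prob_path, log = log)
    obs <- op$observations
    prob <- op$proboscis
  }
  off_tree <- setdiff(unique(traits_tab$species), tree$tip.label)
  if (length(off_tree)) {
    stop_fl("species present in traits but absent from tree: %s",
            paste(off_tree, collapse = ", "),
            class = "floralint_validation_error")
  }
  stages <- config$stages
  report <- list(seed = config$seed)
  results <- list()
  need_int <- any(c("integrate", "pgls", "psem") %in% stages)
  need_pla <- any(c("pla", "pgls", "psem") %in% stages)
  # ---- integration -------------------------------------------------
  int_tab <- NULL
  if (need_int) {
    int_tab <- species_integration(traits_tab, traits = config$traits,
                                   n_boot = config$n_boot,
                                   seed = config$seed)
    log_line(log, "INFO", "integration computed for %d species (%d bootstrap reps)",
             nrow(int_tab), config$n_boot)
    if ("integrate" %in% stages) {
      report$integration <- int_tab
      results$integration <- int_tab
    }
  }
  # ---- PLa ---------------------------------------------------------
  pla_tab <- NULL
  if (need_pla) {
    pla_tab <- assemblage_proboscis(obs, prob,
                                    aggregation = config$aggregation)
    log_line(log, "INFO", "PLa computed for %d species", nrow(pla_tab))
    if ("pla" %in% stages) {
      report$pla <- pla_tab
      results$pla <- pla_tab
    }
  }
  # ---- species-level table ----------------------------------------
  species_tab <- NULL
  if (any(c("pgls", "psem") %in% stages)) {
    agg <- stats::aggregate(traits_tab[, config$traits, drop = FALSE],
                            by = list(species = traits_tab$species),
                            FUN = mean)
    species_tab <- merge(agg,
                         int_tab[, c("species", "percent_INT")],
                         by = "species")
    species_tab <- merge(species_tab, pla_tab[, c("species", "PLa")],
                         by = "species")
    species_tab <- species_tab[match(intersect(tree$tip.label,
                                               species_tab$species),
                                     species_tab$species), , drop = FALSE]
    rownames(species_tab) <- NULL
  }
  # ---- PGLS screen -------------------------------------------------
  screened <- character()
  if (any(c("pgls", "psem") %in% stages)) {
    predictors <- c(config$traits, "PLa")
    rows <- list()
    for (pr in predictors) {
      y <- species_tab$percent_INT
      X <- cbind(`(Intercept)` = 1, x = species_tab[[pr]])
      cmp <- compare_evolutionary_models(y, X, tree,
                                         models = config$models,
                                         species = species_tab$species)
      for (m in names(cmp$fits)) {
        f <- cmp$fits[[m]]
        if (is.null(f)) next
        rows <- c(rows, list(data.frame(
          response = "percent_INT", predictor = pr, model = m,
          parameter = f$parameter %||% NA_real_,
          b = f$coefficients["x", "estimate"],
          se = f$coefficients["x", "se"], t = f$coefficients["x", "t"],
          p = f$coefficients["x", "p"], logLik = f$logLik, AIC = f$AIC,
          selected = identical(m, cmp$best$model), row.names = NULL)))
      }
      ols <- stats::lm(y ~ species_tab[[pr]])
      sm <- summary(ols)$coefficients
      rows <- c(rows, list(data.frame(
        response = "percent_INT", predictor = pr, model = "OLS",
        parameter = NA_real_, b = sm[2L, 1L], se = sm[2L, 2L],
        t = sm[2L, 3L], p = sm[2L, 4L],
        logLik = as.numeric(stats::logLik(ols)), AIC = stats::AIC(ols),
        selected = FALSE, row.names = NULL)))
      p_sel <- cmp$best$coefficients["x", "p"]
      log_line(log, "INFO",
               "PGLS screen: %s ~ %s best model %s, p = %.4g -> %s",
               "percent_INT", pr, cmp$best$model, p_sel,
               if (is.finite(p_sel) && p_sel < config$alpha) "PASS" else "fail")
      if (is.finite(p_sel) && p_sel < config$alpha) {
        screened <- c(screened, pr)
      }
    }
    pgls_tab <- do.call(rbind, rows)
    if ("pgls" %in% stages) {
      report$pgls <- pgls_tab
      results$pgls <- pgls_tab
    }
  }
  # ---- PSEM --------------------------------------------------------
  if ("psem" %in% stages) {
    canonical <- default_modules()
    kept <- intersect(unlist(canonical[-1L]), screened)
    log_line(log, "INFO", "PSEM stage receives traits: %s",
             if (length(kept)) paste(kept, collapse = ", ") else "<none>")
    modules <- canonical
    for (m in c("accessibility", "efficiency")) {
      if (!canonical[[m]] %in% kept) modules[[m]] <- NULL
    }
    att <- intersect(canonical$attractiveness, kept)
    modules$attractiveness <- if (length(att)) canonical$attractiveness else NULL
    n_mod <- sum(!vapply(modules[c("accessibility", "efficiency",
                                   "attractiveness")], is.null, logical(1)),
                 na.rm = TRUE)
    if (n_mod == 0L) {
      log_line(log, "INFO", "no functional module populated; PSEM skipped")
      report$psem <- list(note = "no trait passed the PGLS screen; PSEM not fitted")
    } else {
      fam <- enumerate_candidate_models(modules,
                                        family = config$psem_family)
      log_line(log, "INFO", "candidate PSEM family of %d model(s)",
               length(fam))
      fits <- lapply(fam, fit_psem, data = species_tab, tree = tree,
                     eng = config$eng, alpha = config$alpha)
      names(fits) <- vapply(fam, function(m)
        paste(paste(m$edges$from, m$edges$to, sep = ">"), collapse = ";"),
        character(1))
      sel <- select_best_psem(fits)
      for (i in seq_along(fits)) {
        log_line(log, "INFO", "PSEM %s: C = %.3f, p = %.3f, AIC = %.3f [%s]",
                 names(fits)[i], fits[[i]]$C, fits[[i]]$p, fits[[i]]$AIC,
                 if (fits[[i]]$pass) "pass" else "FAIL")
      }
      report$psem <- list(
        ranking = sel$table,
        note = sel$note,
        best = if (is.null(sel$best)) NULL else list(
          edges = sel$best$model$edges,
          correlated = sel$best$model$correlated,
          coefficients = sel$best$coefficients,
          residual_correlations = sel$best$correlated,
          C = sel$best$C, df = sel$best$df, p = sel$best$p,
          K = sel$best$K, AIC = sel$best$AIC))
      results$psem <- sel
    }
  }
  # ---- outputs -----------------------------------------------------
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(json = file.path(config$out_dir, "report.json"),
                log = file.path(config$out_dir, "log.txt"))
  jsonlite::write_json(report, paths$json, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  write_tsv <- function(df, name) {
    p <- file.path(config$out_dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths[[name]] <<- p
  }
  if (!is.null(report$integration)) write_tsv(report$integration,
                                              "integration.tsv")
  if (!is.null(report$pla)) write_tsv(report$pla, "pla.tsv")
  if (!is.null(report$pgls)) write_tsv(report$pgls, "pgls.tsv")
  if (!is.null(report$psem$ranking)) write_tsv(report$psem$ranking,
                                               "psem_ranking.tsv")
  writeLines(log$lines, paths$log)
  invisible(list(results = results, report = report, paths = paths,
                 log = log$lines, species_table = species_tab,
                 screened = screened))
}
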