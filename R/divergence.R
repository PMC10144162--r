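#' PCA of pooled individuals
#'
#' Principal component analysis of the pooled individuals-by-traits
#' matrix on the correlation scale (columns centred and scaled with N-1
#' denominators). Components are ordered by decreasing variance and the
#' sign of each component is fixed so that its largest-magnitude loading
#' is positive, making loadings reproducible.
#'
#' @param table trait table with >= 2 species.
#' @param traits trait columns; default all trait columns.
#' @return list with `proportions` (variance proportions, sum 1),
#'   `loadings` (traits x components), `scores` (individuals x
#'   components) and `species` (per-individual species labels).
#' @export
divergence_pca <- function(table, traits = NULL) {
  traits <- traits %||% trait_columns(table)
  if (length(unique(table$species)) < 2L) {
    stop_fl("PCA divergence needs >= 2 species",
            class = "floralint_input_error")
  }
  x <- as.matrix(table[, traits, drop = FALSE])
  sds <- apply(x, 2L, sd)
  if (any(sds == 0)) {
    stop_fl("degenerate trait (constant column): %s",
            paste(traits[sds == 0], collapse = ", "),
            class = "floralint_degenerate_trait_error")
  }
  pc <- prcomp(x, center = TRUE, scale. = TRUE)
  flip <- vapply(seq_len(ncol(pc$rotation)), function(j) {
    load <- pc$rotation[, j]
    sign(load[which.max(abs(load))]) < 0
  }, logical(1))
  pc$rotation[, flip] <- -pc$rotation[, flip]
  pc$x[, flip] <- -pc$x[, flip]
  list(proportions = pc$sdev^2 / sum(pc$sdev^2),
       loadings = pc$rotation,
       scores = pc$x,
       species = table$species)
}

#' Per-trait ANOVA with Tukey letters
#'
#' One-way ANOVA of each trait across species (df = k-1, N-k), with a
#' Bonferroni adjustment of the ANOVA p-values across the T traits,
#' Tukey HSD pairwise comparisons at family level 0.05 and a compact
#' letter display per species (insert-and-absorb algorithm; letter sets
#' ordered by species-label order).
#'
#' @inheritParams divergence_pca
#' @param alpha family-wise level of the Tukey comparisons (default
#'   0.05).
#' @return list with `anova` (data.frame: trait, df1, df2, F, p,
#'   p_bonferroni) and `letters` (species x trait matrix of letter
#'   strings).
#' @export
trait_anova_tukey <- function(table, traits = NULL, alpha = 0.05) {
  traits <- traits %||% trait_columns(table)
  species <- factor(table$species, levels = unique(table$species))
  if (nlevels(species) < 2L) {
    stop_fl("ANOVA needs >= 2 species", class = "floralint_input_error")
  }
  counts <- table(species)
  if (any(counts < 2L)) {
    stop_fl("species with a single individual: %s",
            paste(names(counts)[counts < 2L], collapse = ", "),
            class = "floralint_input_error")
  }
  k <- nlevels(species)
  n_tot <- length(species)
  rows <- vector("list", length(traits))
  letters_mat <- matrix(NA_character_, nrow = k, ncol = length(traits),
                        dimnames = list(levels(species), traits))
  for (j in seq_along(traits)) {
    y <- table[[traits[j]]]
    fit <- aov(y ~ species)
    an <- summary(fit)[[1L]]
    Fval <- an[["F value"]][1L]
    pval <- an[["Pr(>F)"]][1L]
    tuk <- TukeyHSD(fit, conf.level = 1 - alpha)$species
    # rows named "b-a"; significant difference when p-adj < alpha
    pair_names <- strsplit(rownames(tuk), "-", fixed = TRUE)
    differ <- matrix(FALSE, k, k, dimnames = list(levels(species),
                                                  levels(species)))
    for (i in seq_along(pair_names)) {
      a <- pair_names[[i]][2L]; b <- pair_names[[i]][1L]
      sig <- is.finite(tuk[i, "p adj"]) && tuk[i, "p adj"] < alpha
      differ[a, b] <- differ[b, a] <- sig
    }
    letters_mat[, j] <- compact_letters(levels(species), differ)
    rows[[j]] <- data.frame(trait = traits[j], df1 = k - 1L,
                            df2 = n_tot - k, F = Fval, p = pval)
  }
  anova_tab <- do.call(rbind, rows)
  anova_tab$p_bonferroni <- pmin(1, anova_tab$p * length(traits))
  list(anova = anova_tab, letters = letters_mat)
}

# Compact letter display by insert-and-absorb: start from one set holding
# all levels; for each significantly different pair split every set that
# still contains both; absorb sets that became subsets of others. Sets
# are ordered by their first member in level order, then lettered a, b,
# c, ...
#' @noRd
compact_letters <- function(levels, differ) {
  sets <- list(levels)
  pairs <- which(upper.tri(differ) & differ, arr.ind = TRUE)
  if (nrow(pairs)) {
    # deterministic processing order: by row then column index
    pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
    for (r in seq_len(nrow(pairs))) {
      a <- levels[pairs[r, 1L]]
      b <- levels[pairs[r, 2L]]
      new_sets <- list()
      for (s in sets) {
        if (a %in% s && b %in% s) {
          new_sets <- c(new_sets, list(setdiff(s, a)), list(setdiff(s, b)))
        } else {
          new_sets <- c(new_sets, list(s))
        }
      }
      # absorb subsets
      keep <- rep(TRUE, length(new_sets))
      for (i in seq_along(new_sets)) {
        for (jj in seq_along(new_sets)) {
          if (i != jj && keep[jj] &&
              all(new_sets[[i]] %in% new_sets[[jj]]) &&
              (length(new_sets[[i]]) < length(new_sets[[jj]]) || i > jj)) {
            keep[i] <- FALSE
            break
          }
        }
      }
      sets <- unique(new_sets[keep])
    }
  }
  first_idx <- vapply(sets, function(s) min(match(s, levels)), numeric(1))
  sets <- sets[order(first_idx)]
  out <- vapply(levels, function(lv) {
    paste0(letters[which(vapply(sets, function(s) lv %in% s, logical(1)))],
           collapse = "")
  }, character(1))
  out
}
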