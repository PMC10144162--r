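#' Guild visitation rates for one plant species
#'
#' The per-period rate of a guild is its visit count divided by the
#' number of open flowers watched in that period; the guild's visitation
#' rate VFi is the mean of per-period rates over all of the species'
#' observation periods, a period without visits by that guild
#' contributing 0 (`aggregation = "mean_rate"`, default). The pooled
#' alternative divides total visits by total flower-periods
#' (`aggregation = "pooled"`).
#'
#' @param obs observation table (see [read_observations()]).
#' @param species_id plant species to summarise.
#' @param guilds guilds to report; defaults to the guilds observed for
#'   this species. Guilds never observed for the species get VFi = 0.
#' @param aggregation `"mean_rate"` or `"pooled"`.
#' @return named numeric vector of VFi, visits per flower per period.
#' @export
visitation_rates <- function(obs, species_id, guilds = NULL,
                             aggregation = c("mean_rate", "pooled")) {
  aggregation <- match.arg(aggregation)
  sub <- obs[obs$species == species_id, , drop = FALSE]
  if (nrow(sub) == 0L) {
    stop_fl("no observations for species '%s'", species_id,
            class = "floralint_input_error")
  }
  guilds <- guilds %||% sort(unique(sub$guild))
  periods <- unique(sub$period)
  n_periods <- length(periods)
  # total open flowers per period (a property of the watch, recorded on
  # every row of that period)
  flowers_per_period <- vapply(periods, function(p) {
    sub$open_flowers[match(p, sub$period)]
  }, numeric(1))
  vf <- vapply(guilds, function(g) {
    rows <- sub[sub$guild == g, , drop = FALSE]
    if (nrow(rows) == 0L) return(0)
    if (aggregation == "mean_rate") {
      sum(rows$visits / rows$open_flowers) / n_periods
    } else {
      sum(rows$visits) / sum(flowers_per_period)
    }
  }, numeric(1))
  setNames(vf, guilds)
}

#' Mean proboscis length per guild
#'
#' @param prob proboscis table (guild, specimen, proboscis_length in
#'   mm).
#' @param guilds guilds to report; default all guilds in `prob`. A
#'   requested guild with no specimens is an error.
#' @return named numeric vector PLi (mm) with attribute `n_specimens`.
#' @export
guild_proboscis_means <- function(prob, guilds = NULL) {
  guilds <- guilds %||% sort(unique(prob$guild))
  missing <- setdiff(guilds, prob$guild)
  if (length(missing)) {
    stop_fl("guild(s) with no proboscis specimens: %s",
            paste(missing, collapse = ", "),
            class = "floralint_input_error")
  }
  pli <- vapply(guilds, function(g)
    mean(prob$proboscis_length[prob$guild == g]), numeric(1))
  n <- vapply(guilds, function(g) sum(prob$guild == g), integer(1))
  structure(setNames(pli, guilds), n_specimens = setNames(n, guilds))
}

#' Composite proboscis length of a pollinator assemblage
#'
#' The visitation-weighted mean proboscis length
#' \deqn{PLa = \sum_i PL_i \, VF_i / VF_n, \qquad VF_n = \sum_i VF_i,}
#' where PLi is the mean proboscis length of guild i and VFi its
#' visitation rate. PLa always lies between the smallest and largest
#' guild mean and is invariant to rescaling all rates by a common
#' factor. Guilds with VFi = 0 are counted in n but contribute nothing.
#'
#' @param PLi named numeric vector of guild mean proboscis lengths (mm).
#' @param VFi numeric vector of guild visitation rates, same order (or
#'   matched by name when both are named).
#' @param species_id optional label stored in the result.
#' @return an `assemblage_summary`: list with `species_id`, `n` (number
#'   of guilds), `VFn`, `PLa` (mm) and the per-guild table.
#' @examples
#' composite_proboscis_length(c(bee = 2, moth = 10), c(bee = 0.3, moth = 0.1))
#' @export
composite_proboscis_length <- function(PLi, VFi,
                                       species_id = NA_character_) {
  if (!is.null(names(PLi)) && !is.null(names(VFi))) {
    if (!setequal(names(PLi), names(VFi))) {
      stop_fl("guild names of PLi and VFi differ",
              class = "floralint_input_error")
    }
    VFi <- VFi[names(PLi)]
  }
  if (length(PLi) != length(VFi) || length(PLi) < 1L) {
    stop_fl("PLi and VFi must be non-empty vectors of equal length",
            class = "floralint_input_error")
  }
  assert_finite_positive(PLi, "guild proboscis length")
  if (any(!is.finite(VFi) | VFi < 0)) {
    stop_fl("visitation rates must be finite and >= 0",
            class = "floralint_input_error")
  }
  VFn <- sum(VFi)
  if (VFn == 0) {
    stop_fl("assemblage visitation rate is zero; PLa is undefined",
            class = "floralint_undefined_pla_error")
  }
  structure(list(species_id = species_id, n = length(PLi), VFn = VFn,
                 PLa = sum(PLi * VFi) / VFn,
                 guilds = data.frame(guild = names(PLi) %||%
                                       as.character(seq_along(PLi)),
                                     PLi = as.numeric(PLi),
                                     VFi = as.numeric(VFi),
                                     row.names = NULL)),
            class = "assemblage_summary")
}

#' @export
print.assemblage_summary <- function(x, ...) {
  cat(sprintf("pollinator assemblage%s: %d guild(s), VFn = %.4g, PLa = %.3f mm\n",
              if (is.na(x$species_id)) "" else sprintf(" [%s]", x$species_id),
              x$n, x$VFn, x$PLa))
  invisible(x)
}

#' Assemblage summary for every plant species
#'
#' Combines [visitation_rates()], [guild_proboscis_means()] and
#' [composite_proboscis_length()] over all species of an observation
#' table. Species whose assemblage visitation rate is zero get `NA` PLa
#' with a warning.
#'
#' @inheritParams visitation_rates
#' @param prob proboscis table.
#' @return data.frame with one row per species: species, n_guilds, VFn,
#'   PLa; per-species `assemblage_summary` objects attached as attribute
#'   `"assemblages"`.
#' @export
assemblage_proboscis <- function(obs, prob,
                                 aggregation = c("mean_rate", "pooled")) {
  aggregation <- match.arg(aggregation)
  sp <- unique(obs$species)
  summaries <- lapply(sp, function(s) {
    vf <- visitation_rates(obs, s, aggregation = aggregation)
    pli <- guild_proboscis_means(prob, guilds = names(vf))
    if (sum(vf) == 0) {
      warning(sprintf("species '%s' has zero total visitation; PLa undefined", s))
      return(NULL)
    }
    composite_proboscis_length(pli, vf, species_id = s)
  })
  out <- data.frame(
    species = sp,
    n_guilds = vapply(summaries, function(a)
      if (is.null(a)) NA_integer_ else a$n, integer(1)),
    VFn = vapply(summaries, function(a)
      if (is.null(a)) NA_real_ else a$VFn, numeric(1)),
    PLa = vapply(summaries, function(a)
      if (is.null(a)) NA_real_ else a$PLa, numeric(1)),
    row.names = NULL
  )
  attr(out, "assemblages") <- summaries
  out
}
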