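#' Canonical floral trait set
#'
#' The eight floral traits measured on every flower, in mm.
#'
#' @return character vector of trait column names.
#' @export
floral_traits <- function() {
  c("corolla_tube_length", "throat_diameter", "anther_height",
    "stigma_height", "upper_lip_length", "upper_lip_width",
    "lower_lip_length", "lower_lip_width")
}

#' @noRd
trait_columns <- function(table) {
  setdiff(names(table), c("species", "individual", "PLa"))
}

#' @noRd
check_numeric_column <- function(df, col, path) {
  x <- df[[col]]
  if (is.numeric(x)) return(x)
  conv <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(conv) & !is.na(x))
  stop_fl("non-numeric value in column '%s' of %s (first at data row %d: '%s')",
          col, path, bad[1L], x[bad[1L]], class = "floralint_parse_error")
}

#' Read and validate a trait table
#'
#' CSV with a header, comma separator, `.` decimal point, UTF-8; columns
#' `species`, `individual` and one numeric column per trait. Validation:
#' all trait values finite and positive, (species, individual) pairs
#' unique, every species with at least 3 individuals (the integration
#' index is undefined below that).
#'
#' @param path CSV file path.
#' @param traits required trait columns (default the canonical eight).
#' @return validated data.frame, row order preserved.
#' @export
read_trait_table <- function(path, traits = floral_traits()) {
  df <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  validate_trait_table(df, traits = traits, where = path)
}

#' @rdname read_trait_table
#' @param table in-memory data.frame to validate.
#' @param where label used in error messages.
#' @export
validate_trait_table <- function(table, traits = floral_traits(),
                                 where = "trait table") {
  missing <- setdiff(c("species", "individual", traits), names(table))
  if (length(missing)) {
    stop_fl("%s is missing required column(s): %s", where,
            paste(missing, collapse = ", "),
            class = "floralint_format_error")
  }
  for (tr in traits) {
    table[[tr]] <- check_numeric_column(table, tr, where)
    assert_finite_positive(table[[tr]], sprintf("trait '%s'", tr))
  }
  key <- paste(table$species, table$individual, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1L]
    stop_fl("duplicate (species, individual) pair in %s: %s", where,
            gsub("\r", " / ", dup), class = "floralint_validation_error")
  }
  counts <- table(table$species)
  if (any(counts < 3L)) {
    stop_fl("species with fewer than 3 individuals: %s",
            paste(names(counts)[counts < 3L], collapse = ", "),
            class = "floralint_validation_error")
  }
  table
}

#' @rdname read_trait_table
#' @export
write_trait_table <- function(table, path) {
  write.csv(table, path, row.names = FALSE, quote = FALSE,
            fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a rooted tree with branch lengths
#'
#' Newick file with a single rooted tree. Branch lengths are required on
#' every edge (no silent unit-branch default: a missing length corrupts
#' every downstream covariance); tip labels must be unique.
#'
#' @param path Newick file path.
#' @param log optional log collector.
#' @return a `phylo` tree.
#' @export
read_phylo_tree <- function(path, log = NULL) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  if (!grepl(";", txt, fixed = TRUE)) {
    stop_fl("Newick parse error in %s: no terminating ';' (offset %d)",
            path, nchar(txt) + 1L, class = "floralint_parse_error")
  }
  open <- lengths(regmatches(txt, gregexpr("(", txt, fixed = TRUE)))
  close <- lengths(regmatches(txt, gregexpr(")", txt, fixed = TRUE)))
  if (open != close) {
    stop_fl("Newick parse error in %s: unbalanced parentheses (%d '(' vs %d ')')",
            path, open, close, class = "floralint_parse_error")
  }
  tree <- tryCatch(ape::read.tree(text = txt), error = function(e) NULL,
                   warning = function(w) NULL)
  if (is.null(tree) || !inherits(tree, "phylo")) {
    stop_fl("Newick parse error in %s", path,
            class = "floralint_parse_error")
  }
  if (is.null(tree$edge.length) ||
      length(tree$edge.length) != nrow(tree$edge) ||
      anyNA(tree$edge.length)) {
    stop_fl("tree in %s has missing branch lengths; lengths are required",
            path, class = "floralint_validation_error")
  }
  if (any(tree$edge.length < 0)) {
    stop_fl("tree in %s has negative branch lengths", path,
            class = "floralint_validation_error")
  }
  if (anyDuplicated(tree$tip.label)) {
    stop_fl("tree in %s has duplicate tip labels", path,
            class = "floralint_validation_error")
  }
  log_line(log, "INFO", "read tree with %d tips from %s",
           length(tree$tip.label), path)
  tree
}

#' @rdname read_phylo_tree
#' @param tree a `phylo` tree to write.
#' @export
write_phylo_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read pollinator observations and proboscis measurements
#'
#' Observation CSV: species, guild, period, visits (non-negative
#' integer), open_flowers (integer >= 1). Proboscis CSV: guild,
#' specimen, proboscis_length (mm > 0). Every guild appearing in the
#' observations should have at least one proboscis specimen; offenders
#' produce a warning listing them.
#'
#' @param obs_path,prob_path CSV file paths.
#' @param log optional log collector.
#' @return list with `observations` and `proboscis` data.frames.
#' @export
read_observations <- function(obs_path, prob_path, log = NULL) {
  obs <- read.csv(obs_path, stringsAsFactors = FALSE,
                  fileEncoding = "UTF-8")
  prob <- read.csv(prob_path, stringsAsFactors = FALSE,
                   fileEncoding = "UTF-8")
  missing <- setdiff(c("species", "guild", "period", "visits",
                       "open_flowers"), names(obs))
  if (length(missing)) {
    stop_fl("%s is missing required column(s): %s", obs_path,
            paste(missing, collapse = ", "),
            class = "floralint_format_error")
  }
  obs$visits <- check_numeric_column(obs, "visits", obs_path)
  obs$open_flowers <- check_numeric_column(obs, "open_flowers", obs_path)
  if (any(obs$visits < 0 | obs$visits != round(obs$visits))) {
    stop_fl("visit counts must be non-negative integers",
            class = "floralint_validation_error")
  }
  if (any(obs$open_flowers < 1 | obs$open_flowers != round(obs$open_flowers))) {
    stop_fl("open_flowers must be integers >= 1",
            class = "floralint_validation_error")
  }
  missing <- setdiff(c("guild", "specimen", "proboscis_length"),
                     names(prob))
  if (length(missing)) {
    stop_fl("%s is missing required column(s): %s", prob_path,
            paste(missing, collapse = ", "),
            class = "floralint_format_error")
  }
  prob$proboscis_length <- check_numeric_column(prob, "proboscis_length",
                                                prob_path)
  assert_finite_positive(prob$proboscis_length, "proboscis length")
  orphan <- setdiff(unique(obs$guild), unique(prob$guild))
  if (length(orphan)) {
    msg <- sprintf("guild(s) observed but without proboscis specimens: %s",
                   paste(orphan, collapse = ", "))
    log_line(log, "WARN", "%s", msg)
    warning(msg)
  }
  log_line(log, "INFO", "read %d observation rows, %d proboscis specimens",
           nrow(obs), nrow(prob))
  list(observations = obs, proboscis = prob)
}

#' @rdname read_observations
#' @param table data.frame to write.
#' @param path output CSV path.
#' @export
write_observation_table <- function(table, path) {
  write.csv(table, path, row.names = FALSE, quote = FALSE,
            fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname read_observations
#' @export
write_proboscis_table <- function(table, path) {
  write.csv(table, path, row.names = FALSE, quote = FALSE,
            fileEncoding = "UTF-8")
  invisible(path)
}
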