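#' Residue selection sets
#'
#' Bundles the three residue-number sets driving the tail-core analysis:
#' the Sm core (C), the basic rim/NTD patch used for the EEC sum (B, a
#' subset of the core), and the acidic tail tip (T). Numbering follows the
#' scheme recorded in `numbering_scheme` (E. coli numbering for the shipped
#' species table).
#'
#' @param core Integer vector of core residue numbers.
#' @param basic_core Integer vector, subset of `core`.
#' @param tail Integer vector of tail residue numbers, disjoint from `core`.
#' @param species Free-text species label.
#' @param numbering_scheme Numbering scheme label (default `"E. coli"`).
#' @return An object of class `selection_sets`.
#' @export
selection_sets <- function(core, basic_core, tail, species = "",
                           numbering_scheme = "E. coli") {
  core <- sort(unique(as.integer(core)))
  basic_core <- sort(unique(as.integer(basic_core)))
  tail <- sort(unique(as.integer(tail)))
  if (length(core) == 0 || length(basic_core) == 0 || length(tail) == 0) {
    abort("core, basic_core and tail must all be non-empty")
  }
  extra <- setdiff(basic_core, core)
  if (length(extra) > 0) {
    abort(paste0("basic_core must be a subset of core; offending residue(s): ",
                 paste(extra, collapse = ", ")))
  }
  overlap <- intersect(core, tail)
  if (length(overlap) > 0) {
    abort(paste0("core and tail must be disjoint; offending residue(s): ",
                 paste(overlap, collapse = ", ")))
  }
  structure(list(core = core, basic_core = basic_core, tail = tail,
                 species = species, numbering_scheme = numbering_scheme),
            class = "selection_sets")
}

#' @export
print.selection_sets <- function(x, ...) {
  fmt <- function(v) {
    if (length(v) > 8) paste0(v[1], "-", v[length(v)], " (", length(v), ")")
    else paste(v, collapse = ", ")
  }
  cat("<selection_sets> ", x$species,
      " [", x$numbering_scheme, " numbering]\n", sep = "")
  cat("  core (C):       ", fmt(x$core), "\n", sep = "")
  cat("  basic core (B): ", fmt(x$basic_core), "\n", sep = "")
  cat("  tail (T):       ", fmt(x$tail), "\n", sep = "")
  invisible(x)
}

#' Load residue selections for a species
#'
#' Reads a selections config (YAML keyed by species with fields `core`,
#' `basic_core`, `tail`; integers or `"a-b"` range strings). The shipped
#' default config covers E. coli, P. aeruginosa, L. monocytogenes,
#' B. subtilis and S. aureus Hfq, all in E. coli numbering.
#'
#' @param species Species name as it appears in the config
#'   (e.g. `"E. coli"`).
#' @param path Optional path to a custom config; default uses the config
#'   shipped with the package.
#' @return A [selection_sets] object.
#' @export
#' @examples
#' load_selections("E. coli")
load_selections <- function(species, path = NULL) {
  path <- path %||% system.file("extdata", "selections.yml",
                                package = "hfqtail", mustWork = TRUE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$species)) abort("selections config has no 'species' block")
  if (!species %in% names(cfg$species)) {
    abort(paste0("unknown species '", species, "'; available: ",
                 paste(names(cfg$species), collapse = ", ")))
  }
  row <- cfg$species[[species]]
  selection_sets(
    core = parse_residue_set(row$core),
    basic_core = parse_residue_set(row$basic_core),
    tail = parse_residue_set(row$tail),
    species = species,
    numbering_scheme = cfg$numbering_scheme %||% "E. coli"
  )
}

#' List species available in a selections config
#' @inheritParams load_selections
#' @return Character vector of species names.
#' @export
available_species <- function(path = NULL) {
  path <- path %||% system.file("extdata", "selections.yml",
                                package = "hfqtail", mustWork = TRUE)
  names(yaml::read_yaml(path)$species)
}

parse_residue_set <- function(x) {
  if (is.null(x)) abort("missing residue set in selections config")
  if (is.numeric(x)) return(as.integer(x))
  out <- integer(0)
  for (tok in unlist(strsplit(as.character(x), "[,;]\\s*"))) {
    tok <- trimws(tok)
    if (grepl("^\\d+\\s*-\\s*\\d+$", tok)) {
      ab <- as.integer(strsplit(tok, "-")[[1]])
      out <- c(out, seq(ab[1], ab[2]))
    } else if (grepl("^\\d+$", tok)) {
      out <- c(out, as.integer(tok))
    } else {
      abort(paste0("cannot parse residue set token: '", tok, "'"))
    }
  }
  out
}
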