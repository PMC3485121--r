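# In-memory representation of rule-based models.
#
# A site graph is a list of molecule instances; each molecule carries a type
# name, an optional compartment tag, and an ordered list of component
# mentions. A component mention has a name, an internal state (NA = wildcard
# / unspecified) and a bond marker:
#   "0"  unbound
#   "+"  bound to an unspecified partner (pattern only)
#   "?"  bond status unspecified (pattern only)
#   "1", "2", ... explicit bond label shared by exactly two endpoints
# A concrete species mentions every component of its type, has no wildcards,
# and is connected.

#' Create a component mention of a site-graph molecule
#'
#' @param name component name (must exist in the molecule's type).
#' @param state internal state label, or `NA` to leave it unspecified
#'   (wildcard in a pattern).
#' @param bond bond marker: `"0"` (unbound), `"+"` (bound to anything),
#'   `"?"` (unspecified), or a positive integer label pairing two endpoints.
#' @return a list of class `sg_comp`.
#' @export
sg_comp <- function(name, state = NA_character_, bond = "0") {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  bond <- as.character(bond)
  if (!grepl("^([0?+]|[1-9][0-9]*)$", bond)) {
    stop("invalid bond marker: ", bond)
  }
  structure(list(name = name, state = as.character(state), bond = bond),
            class = "sg_comp")
}

#' Create a molecule instance for a site graph
#'
#' @param type molecule type name.
#' @param ... component mentions ([sg_comp()]) or character shorthands like
#'   `"y~P!1"`.
#' @param compartment optional compartment tag.
#' @return a list of class `sg_mol`.
#' @export
sg_mol <- function(type, ..., compartment = NA_character_) {
  comps <- lapply(list(...), function(x) {
    if (inherits(x, "sg_comp")) x else parse_comp_shorthand(x)
  })
  structure(list(type = type, compartment = as.character(compartment),
                 comps = comps),
            class = "sg_mol")
}

parse_comp_shorthand <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  m <- regmatches(x, regexec("^([A-Za-z_][A-Za-z0-9_]*)(~[A-Za-z0-9_?]+)?(!(?:[0-9]+|\\+|\\?))?$", x))[[1]]
  if (length(m) == 0L) stop("cannot parse component: ", x)
  state <- if (nzchar(m[3])) sub("^~", "", m[3]) else NA_character_
  if (identical(state, "?")) state <- NA_character_
  bond <- if (nzchar(m[4])) sub("^!", "", m[4]) else "0"
  if (identical(bond, "?")) bond <- "?"
  sg_comp(m[2], state = state, bond = bond)
}

#' Assemble molecules into a site graph
#'
#' Bonds are encoded by shared bond labels on exactly two component mentions.
#'
#' @param ... molecule instances created with [sg_mol()].
#' @return an object of class `site_graph`.
#' @export
site_graph <- function(...) {
  mols <- list(...)
  if (length(mols) == 1L && is.list(mols[[1]]) && !inherits(mols[[1]], "sg_mol")) {
    mols <- mols[[1]]
  }
  stopifnot(all(vapply(mols, inherits, logical(1), "sg_mol")))
  g <- structure(list(mols = mols), class = "site_graph")
  check_bond_labels(g)
  g
}

check_bond_labels <- function(g) {
  labs <- unlist(lapply(g$mols, function(m)
    vapply(m$comps, function(cc) cc$bond, character(1))))
  labs <- labs[!labs %in% c("0", "+", "?")]
  if (length(labs)) {
    tab <- table(labs)
    bad <- names(tab)[tab != 2L]
    if (length(bad)) {
      stop("bond label(s) not shared by exactly two endpoints: ",
           paste(bad, collapse = ", "))
    }
  }
  invisible(g)
}

#' @export
format.site_graph <- function(x, ...) sg_to_text(x)

#' @export
print.site_graph <- function(x, ...) {
  cat("<site_graph> ", sg_to_text(x), "\n", sep = "")
  invisible(x)
}

# Serialize a site graph in the dialect's pattern syntax (molecule order as
# stored; bond labels renumbered in order of first appearance).
sg_to_text <- function(g) {
  relabel <- new.env(parent = emptyenv())
  nxt <- 0L
  mol_txt <- vapply(g$mols, function(m) {
    ct <- vapply(m$comps, function(cc) {
      s <- cc$name
      if (!is.na(cc$state)) s <- paste0(s, "~", cc$state)
      b <- cc$bond
      if (b == "+") {
        s <- paste0(s, "!+")
      } else if (b == "?") {
        s <- paste0(s, "!?")
      } else if (b != "0") {
        if (is.null(relabel[[b]])) {
          nxt <<- nxt + 1L
          relabel[[b]] <- nxt
        }
        s <- paste0(s, "!", relabel[[b]])
      }
      s
    }, character(1))
    txt <- paste0(m$type, "(", paste(ct, collapse = ","), ")")
    if (!is.na(m$compartment)) txt <- paste0(txt, "@", m$compartment)
    txt
  }, character(1))
  paste(mol_txt, collapse = ".")
}

#' Declare a molecule type
#'
#' @param name type name.
#' @param ... components, each either a bare name (pure binding site) or a
#'   shorthand like `"y~U~P"` declaring the ordered state labels.
#' @param compartment home compartment name (default `"C"`).
#' @return a list of class `molecule_type`.
#' @export
molecule_type <- function(name, ..., compartment = "C") {
  comps <- lapply(list(...), function(x) {
    parts <- strsplit(x, "~", fixed = TRUE)[[1]]
    list(name = parts[1], states = if (length(parts) > 1) parts[-1] else character(0))
  })
  nm <- vapply(comps, `[[`, character(1), "name")
  for (cc in comps) {
    if (anyDuplicated(cc$states)) {
      stop("duplicate state labels in component ", cc$name, " of ", name)
    }
  }
  structure(list(name = name, comps = comps, compartment = compartment),
            class = "molecule_type")
}

#' Declare a compartment
#'
#' @param name compartment name (the ERBB model convention uses `Ex`
#'   extracellular, `M` membrane, `C` cytoplasm, `En` endosome, but any
#'   identifier is accepted).
#' @param dimension 2 (surface) or 3 (volume).
#' @param size volume in liters (3-D) or an area-equivalent scale (2-D).
#' @param scale_factor dimensionless multiplier applied to `size` and to
#'   seed-species copy numbers at simulation time.
#' @return a list of class `compartment`.
#' @export
compartment <- function(name, dimension = 3, size = 1e-12, scale_factor = 1) {
  stopifnot(dimension %in% c(2, 3), size > 0, scale_factor > 0)
  structure(list(name = name, dimension = as.integer(dimension),
                 size = size, scale_factor = scale_factor),
            class = "compartment")
}

#' Declare a model parameter
#'
#' @param name parameter name.
#' @param value nonnegative numeric value.
#' @param units one of `"(molecules/cell)^-1 s^-1"`, `"s^-1"`,
#'   `"molecules/cell"`, `"dimensionless"`, or `NA`.
#' @param class optional parameter class name (see [parameter_classes()]).
#' @return a list of class `rb_parameter`.
#' @export
rb_parameter <- function(name, value, units = NA_character_, class = NA_character_) {
  stopifnot(is.numeric(value), length(value) == 1L, value >= 0)
  structure(list(name = name, value = value, units = units, class = class),
            class = "rb_parameter")
}

#' Declare an observable
#'
#' @param name observable name.
#' @param kind `"Molecules"` (sum of pattern embedding counts) or
#'   `"Species"` (number of distinct complexes containing a match).
#' @param patterns list of pattern [site_graph()]s (or pattern strings).
#' @return a list of class `rb_observable`.
#' @export
rb_observable <- function(name, kind = c("Molecules", "Species"), patterns) {
  kind <- match.arg(kind)
  if (inherits(patterns, "site_graph")) patterns <- list(patterns)
  patterns <- lapply(patterns, function(p)
    if (is.character(p)) parse_pattern(p) else p)
  structure(list(name = name, kind = kind, patterns = patterns),
            class = "rb_observable")
}

#' Declare a reaction rule
#'
#' A rule is unidirectional; reversible rules are stored as two rules linked
#' via `reversible_partner` (see [rb_model()]), which the detailed-balance
#' machinery relies on.
#'
#' @param name rule name.
#' @param reactants list of 0, 1, or 2 pattern [site_graph()]s.
#' @param products list of product pattern [site_graph()]s.
#' @param rate_param name of a declared parameter (or a numeric literal).
#' @param reversible_partner optional name of the paired reverse rule.
#' @return a list of class `rb_rule`; transformations are derived lazily by
#'   [derive_transformations()].
#' @export
rb_rule <- function(name, reactants, products, rate_param,
                    reversible_partner = NA_character_) {
  as_pat <- function(p) if (is.character(p)) parse_pattern(p) else p
  if (inherits(reactants, "site_graph") || is.character(reactants)) reactants <- list(reactants)
  if (inherits(products, "site_graph") || is.character(products)) products <- list(products)
  reactants <- lapply(reactants, as_pat)
  products <- lapply(products, as_pat)
  if (length(reactants) > 2L) stop("rule ", name, ": at most 2 reactant patterns (elementary mass action)")
  structure(list(name = name, reactants = reactants, products = products,
                 rate_param = rate_param,
                 reversible_partner = reversible_partner),
            class = "rb_rule")
}

#' Assemble a rule-based model
#'
#' @param molecule_types list of [molecule_type()]s.
#' @param compartments list of [compartment()]s (optional).
#' @param parameters list of [rb_parameter()]s.
#' @param seed_species list of `list(species = <site_graph or text>, copies = <count>)`.
#' @param rules list of [rb_rule()]s.
#' @param observables list of [rb_observable()]s.
#' @return an object of class `rb_model`.
#' @export
rb_model <- function(molecule_types = list(), compartments = list(),
                     parameters = list(), seed_species = list(),
                     rules = list(), observables = list()) {
  seed_species <- lapply(seed_species, function(s) {
    if (is.character(s$species)) s$species <- parse_pattern(s$species)
    s
  })
  m <- structure(list(
    molecule_types = setNames(molecule_types,
                              vapply(molecule_types, `[[`, character(1), "name")),
    compartments = setNames(compartments,
                            vapply(compartments, `[[`, character(1), "name")),
    parameters = setNames(parameters,
                          vapply(parameters, `[[`, character(1), "name")),
    seed_species = seed_species,
    rules = setNames(rules, vapply(rules, `[[`, character(1), "name")),
    observables = setNames(observables,
                           vapply(observables, `[[`, character(1), "name"))
  ), class = "rb_model")
  m
}

#' @export
print.rb_model <- function(x, ...) {
  cat("<rb_model> ",
      length(x$molecule_types), " molecule types, ",
      length(x$rules), " rules, ",
      length(x$parameters), " parameters, ",
      length(x$seed_species), " seed species, ",
      length(x$observables), " observables\n", sep = "")
  invisible(x)
}

#' Look up a parameter value, allowing numeric literals
#' @noRd
param_value <- function(model, rate_param, overrides = NULL) {
  if (is.numeric(rate_param)) return(rate_param)
  if (!is.null(overrides) && rate_param %in% names(overrides)) {
    return(overrides[[rate_param]])
  }
  suppressWarnings(v <- as.numeric(rate_param))
  if (!is.na(v)) return(v)
  p <- model$parameters[[rate_param]]
  if (is.null(p)) stop("undeclared parameter: ", rate_param)
  p$value
}
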