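# Model validation: machine-readable diagnostics instead of exceptions.
# A model with no error-severity diagnostics is accepted by both simulators.

diag_row <- function(severity, location, message) {
  data.frame(severity = severity, location = location, message = message,
             stringsAsFactors = FALSE)
}

diag_loc <- function(entity, fallback) {
  sp <- attr(entity, "span")
  if (!is.null(sp)) paste0("line ", sp$line) else fallback
}

#' Validate a model
#'
#' Checks every structural invariant: unique names, resolvable
#' cross-references, concrete and connected seed species, at most one bond
#' per component endpoint, declared rate parameters, derivable rule diffs.
#'
#' @param model an [rb_model()].
#' @return data frame with columns `severity` (`"error"`, `"warning"`,
#'   `"note"`), `location`, `message`; zero rows means the model is valid.
#' @export
validate_model <- function(model) {
  d <- diag_row(character(0), character(0), character(0))
  push <- function(sev, loc, msg) d <<- rbind(d, diag_row(sev, loc, msg))

  for (nmset in list(c("molecule_types", "molecule type"),
                     c("parameters", "parameter"),
                     c("compartments", "compartment"),
                     c("rules", "rule"),
                     c("observables", "observable"))) {
    nms <- names(model[[nmset[1]]])
    for (dup in unique(nms[duplicated(nms)])) {
      push("error", dup, paste0("duplicate ", nmset[2], " name"))
    }
  }

  comp_names <- names(model$compartments)
  for (mt in model$molecule_types) {
    cn <- vapply(mt$comps, `[[`, character(1), "name")
    for (dup in unique(cn[duplicated(cn)])) {
      push("note", mt$name,
           paste0("components named '", dup, "' are interchangeable duplicates"))
    }
    if (length(comp_names) && !mt$compartment %in% comp_names) {
      push("error", mt$name,
           paste0("home compartment '", mt$compartment, "' is not declared"))
    }
  }

  for (p in model$parameters) {
    if (p$value < 0) push("error", p$name, "parameter value must be nonnegative")
  }

  reg <- tryCatch(compile_registry(model), error = function(e) NULL)
  if (is.null(reg)) {
    push("error", "molecule types", "cannot index molecule types")
    return(d)
  }

  for (i in seq_along(model$seed_species)) {
    s <- model$seed_species[[i]]
    loc <- diag_loc(s, paste0("seed species ", i))
    err <- tryCatch({ compile_species(s$species, reg); NULL },
                    error = function(e) conditionMessage(e))
    if (!is.null(err)) push("error", loc, err)
    copies <- s$copies
    if (is.character(copies)) {
      if (is.null(model$parameters[[copies]])) {
        push("error", loc, paste0("copy-number parameter '", copies, "' is not declared"))
      } else copies <- model$parameters[[copies]]$value
    }
    if (is.numeric(copies) && (copies < 0 || copies != round(copies))) {
      push("error", loc, "copy number must be a nonnegative integer")
    }
  }

  for (r in model$rules) {
    loc <- diag_loc(r, r$name)
    if (is.character(r$rate_param) &&
        is.na(suppressWarnings(as.numeric(r$rate_param))) &&
        is.null(model$parameters[[r$rate_param]])) {
      push("error", loc, paste0("rate parameter '", r$rate_param, "' is not declared"))
    }
    if (!is.na(r$reversible_partner) &&
        is.null(model$rules[[r$reversible_partner]])) {
      push("error", loc, paste0("reversible partner '", r$reversible_partner,
                                "' is not declared"))
    }
    cps <- lapply(c(r$reactants, r$products), function(p)
      tryCatch(compile_pattern(p, reg), error = function(e) conditionMessage(e)))
    bad <- vapply(cps, is.character, logical(1))
    for (msg in unlist(cps[bad])) push("error", loc, msg)
    if (!any(bad)) {
      for (q in seq_along(r$reactants)) {
        if (!pattern_connected(cps[[q]])) {
          push("error", loc, paste0("reactant pattern ", q, " is not connected"))
        }
      }
      err <- tryCatch({ derive_transformations(r$reactants, r$products); NULL },
                      error = function(e) conditionMessage(e))
      if (!is.null(err)) push("error", loc, err)
    }
  }

  for (ob in model$observables) {
    loc <- diag_loc(ob, ob$name)
    for (p in ob$patterns) {
      err <- tryCatch({ compile_pattern(p, reg); NULL },
                      error = function(e) conditionMessage(e))
      if (!is.null(err)) push("error", loc, err)
    }
  }
  rownames(d) <- NULL
  d
}
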