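# Reader/writer for the plain-text BNGL-subset dialect.
#
# Supported blocks: parameters, compartments (optional), molecule types,
# seed species, observables, reaction rules. Molecule syntax is
# Name(comp~state!bond,...)[@Compartment]; operators "+", "->", "<->", ".";
# "!+" bound-to-anything, "!?" bond unspecified, omitted state = wildcard in
# patterns. Rate expressions are parameter names or numeric literals.
# Comments start with "#". Reversible rules become two linked unidirectional
# rules. "0" denotes an empty reaction side.

span <- function(line, column = 1L, snippet = "") {
  list(line = as.integer(line), column = as.integer(column), snippet = snippet)
}

syntax_error <- function(msg, line, column = 1L, snippet = "") {
  stop(sprintf("syntax error at line %d, column %d: %s [%s]",
               line, column, msg, snippet), call. = FALSE)
}

#' Parse a single pattern or species expression
#'
#' @param text pattern expression, e.g. `"A(b!1).B(a!1)"` or `"R(y~P!+)"`.
#' @return a [site_graph()]; bond wildcards and unspecified states are
#'   preserved as pattern flags.
#' @export
parse_pattern <- function(text) {
  text <- trimws(text)
  if (identical(text, "0") || !nzchar(text)) {
    return(structure(list(mols = list()), class = "site_graph"))
  }
  mol_txts <- split_top(text, ".")
  mols <- lapply(mol_txts, parse_molecule_text, full = text)
  site_graph(mols)
}

# split on sep outside parentheses
split_top <- function(text, sep) {
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  cuts <- integer(0)
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch == "(") depth <- depth + 1L
    else if (ch == ")") depth <- depth - 1L
    else if (ch == sep && depth == 0L) cuts <- c(cuts, i)
    if (depth < 0L) stop("unbalanced parentheses in: ", text, call. = FALSE)
  }
  if (depth != 0L) stop("unbalanced parentheses in: ", text, call. = FALSE)
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts - 1L, length(chars))
  vapply(seq_along(starts), function(j)
    paste(chars[seq(starts[j], ends[j])], collapse = ""), character(1))
}

parse_molecule_text <- function(txt, full = txt) {
  txt <- trimws(txt)
  m <- regmatches(txt, regexec(
    "^([A-Za-z_][A-Za-z0-9_]*)\\(([^()]*)\\)(@([A-Za-z_][A-Za-z0-9_]*))?$", txt))[[1]]
  if (length(m) == 0L) stop("cannot parse molecule '", txt, "' in: ", full,
                            call. = FALSE)
  comp_txt <- m[3]
  comps <- if (nzchar(trimws(comp_txt))) {
    lapply(trimws(strsplit(comp_txt, ",", fixed = TRUE)[[1]]), parse_comp_shorthand)
  } else list()
  structure(list(type = m[2],
                 compartment = if (nzchar(m[5])) m[5] else NA_character_,
                 comps = comps),
            class = "sg_mol")
}

#' Parse a model from dialect text
#'
#' @param text character scalar (or vector of lines) of model source.
#' @return a validated [rb_model()]; each entity carries a source span
#'   attribute (`line`, `column`, `snippet`) for diagnostics.
#' @export
parse_model <- function(text) {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  lines_clean <- sub("#.*$", "", lines)
  blocks <- list()
  current <- NULL
  current_lines <- list()
  for (i in seq_along(lines_clean)) {
    ln <- trimws(lines_clean[i])
    if (!nzchar(ln)) next
    bm <- regmatches(ln, regexec("^begin\\s+(.+)$", ln))[[1]]
    em <- regmatches(ln, regexec("^end\\s+(.+)$", ln))[[1]]
    if (length(bm)) {
      if (!is.null(current)) syntax_error("nested block", i, 1L, ln)
      nm <- trimws(bm[2])
      if (nm %in% names(blocks)) syntax_error(paste0("duplicate block '", nm, "'"), i, 1L, ln)
      current <- nm
      current_lines <- list()
    } else if (length(em)) {
      if (is.null(current) || trimws(em[2]) != current) {
        syntax_error("unmatched end of block", i, 1L, ln)
      }
      blocks[[current]] <- current_lines
      current <- NULL
    } else {
      if (is.null(current)) syntax_error("content outside any block", i, 1L, ln)
      current_lines[[length(current_lines) + 1L]] <- list(line = i, text = ln)
    }
  }
  if (!is.null(current)) {
    syntax_error(paste0("block '", current, "' is never closed"),
                 length(lines), 1L, current)
  }
  known <- c("parameters", "compartments", "molecule types", "seed species",
             "observables", "reaction rules")
  bad <- setdiff(names(blocks), known)
  if (length(bad)) stop("unknown block(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)

  parameters <- lapply(blocks[["parameters"]] %||% list(), function(e) {
    toks <- strsplit(e$text, "\\s+")[[1]]
    if (length(toks) != 2L) syntax_error("expected 'name value'", e$line, 1L, e$text)
    v <- suppressWarnings(as.numeric(toks[2]))
    if (is.na(v)) syntax_error("parameter value must be numeric", e$line, 1L, e$text)
    p <- rb_parameter(toks[1], v)
    attr(p, "span") <- span(e$line, 1L, e$text)
    p
  })

  compartments <- lapply(blocks[["compartments"]] %||% list(), function(e) {
    toks <- strsplit(e$text, "\\s+")[[1]]
    if (!length(toks) %in% c(3L, 4L)) {
      syntax_error("expected 'name dimension size [scale]'", e$line, 1L, e$text)
    }
    cm <- compartment(toks[1], as.integer(toks[2]), as.numeric(toks[3]),
                      if (length(toks) == 4L) as.numeric(toks[4]) else 1)
    attr(cm, "span") <- span(e$line, 1L, e$text)
    cm
  })

  molecule_types <- lapply(blocks[["molecule types"]] %||% list(), function(e) {
    txt <- e$text
    home <- "C"
    am <- regmatches(txt, regexec("^(.*)\\s+@([A-Za-z_][A-Za-z0-9_]*)$", txt))[[1]]
    if (length(am)) { txt <- trimws(am[2]); home <- am[3] }
    m <- regmatches(txt, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\(([^()]*)\\)$", txt))[[1]]
    if (length(m) == 0L) syntax_error("cannot parse molecule type", e$line, 1L, e$text)
    comps <- if (nzchar(trimws(m[3]))) trimws(strsplit(m[3], ",")[[1]]) else character(0)
    mt <- do.call(molecule_type, c(list(m[2]), as.list(comps),
                                   list(compartment = home)))
    attr(mt, "span") <- span(e$line, 1L, e$text)
    mt
  })

  seed_species <- lapply(blocks[["seed species"]] %||% list(), function(e) {
    m <- regmatches(e$text, regexec("^(\\S+)\\s+(\\S+)$", e$text))[[1]]
    if (length(m) == 0L) syntax_error("expected 'species copies'", e$line, 1L, e$text)
    copies <- suppressWarnings(as.numeric(m[3]))
    s <- list(species = with_span(parse_pattern_at(m[2], e), e),
              copies = if (is.na(copies)) m[3] else copies)
    attr(s, "span") <- span(e$line, 1L, e$text)
    s
  })

  observables <- lapply(blocks[["observables"]] %||% list(), function(e) {
    toks <- strsplit(e$text, "\\s+")[[1]]
    if (length(toks) < 3L || !toks[1] %in% c("Molecules", "Species")) {
      syntax_error("expected 'Molecules|Species name pattern...'", e$line, 1L, e$text)
    }
    ob <- rb_observable(toks[2], toks[1],
                        lapply(toks[-(1:2)], parse_pattern_at, entry = e))
    attr(ob, "span") <- span(e$line, 1L, e$text)
    ob
  })

  rules <- list()
  for (e in blocks[["reaction rules"]] %||% list()) {
    rules <- c(rules, parse_rule_line(e))
  }

  m <- rb_model(molecule_types = molecule_types, compartments = compartments,
                parameters = parameters, seed_species = seed_species,
                rules = rules, observables = observables)
  m
}

with_span <- function(x, e) { attr(x, "span") <- span(e$line, 1L, e$text); x }

parse_pattern_at <- function(txt, entry) {
  tryCatch(parse_pattern(txt), error = function(err) {
    syntax_error(conditionMessage(err), entry$line, 1L, entry$text)
  })
}

rate_token <- "[A-Za-z0-9_.eE+-]+"

parse_rule_line <- function(e) {
  txt <- e$text
  name <- NULL
  nm <- regmatches(txt, regexec("^([A-Za-z_][A-Za-z0-9_@=]*)\\s*:\\s*(.*)$", txt))[[1]]
  if (length(nm)) { name <- nm[2]; txt <- nm[3] }
  rev <- grepl("<->", txt, fixed = TRUE)
  op <- if (rev) "<->" else "->"
  if (!grepl(op, txt, fixed = TRUE)) {
    syntax_error("rule must contain '->' or '<->'", e$line, 1L, e$text)
  }
  sides <- strsplit(txt, op, fixed = TRUE)[[1]]
  if (length(sides) != 2L) syntax_error("malformed rule", e$line, 1L, e$text)
  lhs_txt <- trimws(sides[1])
  rhs_all <- trimws(sides[2])
  if (rev) {
    m <- regmatches(rhs_all, regexec(
      paste0("^(.*?)\\s+(", rate_token, ")\\s*,\\s*(", rate_token, ")$"), rhs_all))[[1]]
    if (length(m) == 0L) syntax_error("reversible rule needs 'kf, kr'", e$line, 1L, e$text)
    rhs_txt <- trimws(m[2]); kf <- m[3]; kr <- m[4]
  } else {
    m <- regmatches(rhs_all, regexec(
      paste0("^(.*?)\\s+(", rate_token, ")$"), rhs_all))[[1]]
    if (length(m) == 0L) syntax_error("rule needs a rate constant", e$line, 1L, e$text)
    rhs_txt <- trimws(m[2]); kf <- m[3]; kr <- NULL
  }
  parse_side <- function(stxt) {
    if (identical(stxt, "0")) return(list())
    lapply(trimws(split_top(gsub("\\s+", "", stxt), "+")), parse_pattern_at, entry = e)
  }
  lhs <- parse_side(lhs_txt)
  rhs <- parse_side(rhs_txt)
  if (is.null(name)) name <- paste0("rule_L", e$line)
  fwd <- rb_rule(name, lhs, rhs, kf,
                 reversible_partner = if (rev) paste0(name, "_rev") else NA_character_)
  attr(fwd, "span") <- span(e$line, 1L, e$text)
  if (!rev) return(list(fwd))
  bwd <- rb_rule(paste0(name, "_rev"), rhs, lhs, kr, reversible_partner = name)
  attr(bwd, "span") <- span(e$line, 1L, e$text)
  list(fwd, bwd)
}

#' Serialize a model to dialect text
#'
#' The output is deterministic (stable block and entry ordering) and
#' round-trips: `parse_model(write_model(m))` is structurally identical to
#' `m`. Reversible rule pairs are re-joined into a single `<->` line.
#'
#' @param model an [rb_model()].
#' @return character scalar of model source text.
#' @export
write_model <- function(model) {
  out <- character(0)
  emit <- function(...) out <<- c(out, paste0(...))
  if (length(model$parameters)) {
    emit("begin parameters")
    for (p in model$parameters) emit("  ", p$name, " ", format(p$value, digits = 17))
    emit("end parameters")
  }
  if (length(model$compartments)) {
    emit("begin compartments")
    for (cm in model$compartments) {
      emit("  ", cm$name, " ", cm$dimension, " ", format(cm$size, digits = 17),
           if (cm$scale_factor != 1) paste0(" ", format(cm$scale_factor, digits = 17)) else "")
    }
    emit("end compartments")
  }
  emit("begin molecule types")
  for (mt in model$molecule_types) {
    ct <- vapply(mt$comps, function(cc)
      paste(c(cc$name, cc$states), collapse = "~"), character(1))
    emit("  ", mt$name, "(", paste(ct, collapse = ","), ")",
         if (!identical(mt$compartment, "C")) paste0(" @", mt$compartment) else "")
  }
  emit("end molecule types")
  if (length(model$seed_species)) {
    emit("begin seed species")
    for (s in model$seed_species) {
      emit("  ", sg_to_text(s$species), " ",
           if (is.character(s$copies)) s$copies else format(s$copies, digits = 17))
    }
    emit("end seed species")
  }
  if (length(model$observables)) {
    emit("begin observables")
    for (ob in model$observables) {
      emit("  ", ob$kind, " ", ob$name, " ",
           paste(vapply(ob$patterns, sg_to_text, character(1)), collapse = " "))
    }
    emit("end observables")
  }
  if (length(model$rules)) {
    emit("begin reaction rules")
    done <- character(0)
    for (r in model$rules) {
      if (r$name %in% done) next
      side_txt <- function(pats) {
        if (!length(pats)) return("0")
        paste(vapply(pats, sg_to_text, character(1)), collapse = " + ")
      }
      partner <- if (!is.na(r$reversible_partner)) model$rules[[r$reversible_partner]] else NULL
      if (!is.null(partner)) {
        emit("  ", r$name, ": ", side_txt(r$reactants), " <-> ", side_txt(r$products),
             " ", as.character(r$rate_param), ", ", as.character(partner$rate_param))
        done <- c(done, r$name, partner$name)
      } else {
        emit("  ", r$name, ": ", side_txt(r$reactants), " -> ", side_txt(r$products),
             " ", as.character(r$rate_param))
        done <- c(done, r$name)
      }
    }
    emit("end reaction rules")
  }
  paste0(paste(out, collapse = "\n"), "\n")
}
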