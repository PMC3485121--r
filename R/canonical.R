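# Canonical labeling of concrete species by iterative neighborhood (color)
# refinement followed by exhaustive tie-breaking within color classes. The
# species arising in rule-based signaling models are small complexes (chains
# and trees of at most tens of molecules), so correctness is preferred over
# asymptotic sophistication: the label is the lexicographic minimum of the
# serialization over all molecule orderings compatible with the refined
# color partition, which is an isomorphism-invariant set of orderings.

canonical_cap <- 20000L  # maximum tie-break orderings explored

# Canonical label of a compiled species (possibly disconnected mixture slice
# is not allowed here; use canonical_multiset for reaction sides).
canonical_label_cs <- function(cs, reg) {
  k <- cs$k
  if (k == 0L) return("")
  # initial colors: full per-molecule annotation
  col <- vapply(seq_len(k), function(i) {
    tid <- cs$typ[i]
    nc <- length(reg$types[[tid]]$comp_names)
    paste(reg$types[[tid]]$name, cs$compart[i],
          paste(cs$st[i, seq_len(nc)], collapse = ","),
          paste(as.integer(cs$bmol[i, seq_len(nc)] > 0L), collapse = ","),
          sep = "|")
  }, character(1))
  # refinement
  for (iter in seq_len(k)) {
    newcol <- vapply(seq_len(k), function(i) {
      tid <- cs$typ[i]
      nc <- length(reg$types[[tid]]$comp_names)
      sig <- character(0)
      for (s in seq_len(nc)) {
        pm <- cs$bmol[i, s]
        if (pm > 0L) sig <- c(sig, paste(s, col[pm], cs$bcomp[i, s], sep = "^"))
      }
      paste(col[i], paste(sort(sig), collapse = ";"), sep = "||")
    }, character(1))
    if (length(unique(newcol)) == length(unique(col))) { col <- newcol; break }
    col <- newcol
  }
  # classes ordered by (invariant) color string
  classes <- split(seq_len(k), col)
  classes <- classes[order(names(classes))]
  sizes <- vapply(classes, length, integer(1))
  n_orderings <- prod(factorial(sizes))
  if (n_orderings > canonical_cap) {
    stop("species too symmetric for canonical labeling (",
         format(n_orderings), " candidate orderings)")
  }
  perms_of <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms_of(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    }
    out
  }
  class_perms <- lapply(classes, perms_of)
  best <- NULL
  idx <- rep(1L, length(classes))
  repeat {
    ord <- unlist(lapply(seq_along(classes), function(ci)
      class_perms[[ci]][[idx[ci]]]), use.names = FALSE)
    s <- serialize_ordering(cs, reg, ord)
    if (is.null(best) || s < best) best <- s
    # advance mixed-radix counter
    ci <- 1L
    while (ci <= length(classes)) {
      idx[ci] <- idx[ci] + 1L
      if (idx[ci] <= length(class_perms[[ci]])) break
      idx[ci] <- 1L
      ci <- ci + 1L
    }
    if (ci > length(classes)) break
  }
  best
}

serialize_ordering <- function(cs, reg, ord) {
  pos <- integer(cs$k)
  pos[ord] <- seq_along(ord)
  lab <- 0L
  seen <- new.env(parent = emptyenv())
  out <- character(length(ord))
  for (q in seq_along(ord)) {
    i <- ord[q]
    tid <- cs$typ[i]
    tinfo <- reg$types[[tid]]
    nc <- length(tinfo$comp_names)
    ct <- character(nc)
    for (s in seq_len(nc)) {
      x <- tinfo$comp_names[s]
      if (cs$st[i, s] > 0L) x <- paste0(x, "~", tinfo$comp_states[[s]][cs$st[i, s]])
      pm <- cs$bmol[i, s]
      if (pm > 0L) {
        ps <- cs$bcomp[i, s]
        e <- rbind(c(pos[i], s), c(pos[pm], ps))
        e <- e[order(e[, 1], e[, 2]), , drop = FALSE]
        key <- paste(e[1, 1], e[1, 2], e[2, 1], e[2, 2], sep = ":")
        if (is.null(seen[[key]])) { lab <- lab + 1L; seen[[key]] <- lab }
        x <- paste0(x, "!", seen[[key]])
      }
      ct[s] <- x
    }
    txt <- paste0(tinfo$name, "(", paste(ct, collapse = ","), ")")
    if (!is.na(cs$compart[i])) txt <- paste0(txt, "@", cs$compart[i])
    out[q] <- txt
  }
  paste(out, collapse = ".")
}

#' Canonical label of a concrete species
#'
#' Two concrete, connected species graphs receive the same label if and only
#' if they are isomorphic; the label is a valid species expression in the
#' dialect and is stable across runs and platforms.
#'
#' @param species a concrete connected [site_graph()] or species string.
#' @param model an [rb_model()] declaring the molecule types.
#' @return character scalar.
#' @export
canonical_label <- function(species, model) {
  reg <- compile_registry(model)
  if (is.character(species)) species <- parse_pattern(species)
  has_wild <- any(vapply(species$mols, function(m)
    any(vapply(m$comps, function(cc) cc$bond %in% c("+", "?"), logical(1))),
    logical(1)))
  if (has_wild) stop("canonical_label requires a concrete species (no wildcards)")
  cs <- compile_species(species, reg, require_connected = TRUE)
  canonical_label_cs(cs, reg)
}

# Canonical label for a multiset of species (a reaction side): per-component
# canonical labels, sorted and joined with " + ".
canonical_multiset <- function(css, reg) {
  paste(sort(vapply(css, canonical_label_cs, character(1), reg = reg)),
        collapse = " + ")
}
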