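# Site-graph pattern matching: embedding enumeration into concrete mixtures,
# exact pattern isomorphism (automorphism counting), connectivity.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Enumerate injective assignments of the mentions of pattern molecule p
# (compiled pattern cp) onto the component slots of target molecule t in
# mixture mix. `forced` is a named map mention-index -> slot forced by an
# already-matched bond. Returns a list of integer vectors (mention -> slot).
enum_mention_assignments <- function(cp, p, mix, t, forced = NULL) {
  mens <- cp$men[[p]]
  nm <- length(mens)
  if (nm == 0L) return(list(integer(0)))
  out <- list()
  slots <- integer(nm)
  rec <- function(j, usedslots) {
    if (j > nm) {
      out[[length(out) + 1L]] <<- slots[seq_len(nm)]
      return(invisible())
    }
    men <- mens[[j]]
    fs <- forced[[as.character(j)]]
    for (q in seq_along(men$cand)) {
      s <- men$cand[q]
      if (s %in% usedslots) next
      if (!is.null(fs) && s != fs) next
      # state constraint
      if (!is.na(men$state_label) && mix$st[t, s] != men$st_code[q]) next
      # local bond constraint
      b <- mix$bmol[t, s]
      ok <- switch(men$kind,
                   "0" = b == 0L,
                   "+" = b > 0L,
                   "?" = TRUE,
                   "b" = b > 0L)
      if (!ok) next
      slots[j] <<- s
      rec(j + 1L, c(usedslots, s))
    }
    invisible()
  }
  rec(1L, integer(0))
  out
}

# Core matcher: all embeddings of compiled pattern cp into mixture mix.
# `restrict` limits every matched molecule to the given set; `roots` limits
# candidates for search roots. An embedding is list(mol = integer k,
# slot = list of mention->slot integer vectors).
match_pattern <- function(cp, mix, restrict = NULL, roots = NULL) {
  k <- cp$k
  if (k == 0L) return(list())
  if (is.null(restrict)) {
    alive <- which(mix$typ > 0L)
  } else {
    restrict <- as.integer(restrict)
    alive <- restrict[mix$typ[restrict] > 0L]
  }
  # vectorized fast path: single molecule, unambiguous component slots,
  # no intramolecular bond constraints
  if (k == 1L && nrow(cp$bonds) == 0L &&
      all(vapply(cp$men[[1]], function(m) length(m$cand) == 1L, logical(1)))) {
    cand <- alive[mix$typ[alive] == cp$typ[1]]
    if (!is.null(roots)) cand <- intersect(cand, roots)
    if (!is.na(cp$compart[1])) cand <- cand[mix$compart[cand] == cp$compart[1]]
    slotvec <- vapply(cp$men[[1]], function(m) m$cand, integer(1))
    if (anyDuplicated(slotvec)) return(list())
    if (length(cand)) {
      keep <- rep(TRUE, length(cand))
      for (q in seq_along(cp$men[[1]])) {
        men <- cp$men[[1]][[q]]
        s <- slotvec[q]
        if (!is.na(men$state_label)) {
          keep <- keep & mix$st[cand, s] == men$st_code[1]
        }
        b <- mix$bmol[cand, s]
        keep <- keep & switch(men$kind, "0" = b == 0L, "+" = b > 0L,
                              "?" = TRUE, "b" = b > 0L)
      }
      cand <- cand[keep]
    }
    return(lapply(cand, function(t) list(mol = t, slot = list(slotvec))))
  }
  plan <- cp$plan
  res <- list()
  amol <- integer(k)
  aslot <- vector("list", k)

  check_back_edges <- function() {
    nb <- cp$bonds
    if (!nrow(nb)) return(TRUE)
    for (r in seq_len(nrow(nb))) {
      mi <- nb[r, 1]; ci <- nb[r, 2]; mj <- nb[r, 3]; cj <- nb[r, 4]
      si <- aslot[[mi]][ci]; sj <- aslot[[mj]][cj]
      if (mix$bmol[amol[mi], si] != amol[mj] ||
          mix$bcomp[amol[mi], si] != sj) return(FALSE)
    }
    TRUE
  }

  rec <- function(step) {
    if (step > k) {
      if (check_back_edges()) {
        res[[length(res) + 1L]] <<- list(mol = amol, slot = aslot)
      }
      return(invisible())
    }
    p <- plan$order[step]
    er <- plan$entry[step]
    if (er == 0L) {
      cand <- alive[mix$typ[alive] == cp$typ[p]]
      if (!is.null(roots) && step == 1L) cand <- intersect(cand, roots)
      for (t in cand) {
        if (t %in% amol[seq_len(k)][amol > 0L]) next
        if (!is.na(cp$compart[p]) && mix$compart[t] != cp$compart[p]) next
        for (as_ in enum_mention_assignments(cp, p, mix, t)) {
          amol[p] <<- t; aslot[[p]] <<- as_
          rec(step + 1L)
        }
        amol[p] <<- 0L
      }
    } else {
      b <- cp$bonds[er, ]
      if (b[3] == p) { pp <- b[1]; ci <- b[2]; cj <- b[4] }
      else           { pp <- b[3]; ci <- b[4]; cj <- b[2] }
      si <- aslot[[pp]][ci]
      t <- mix$bmol[amol[pp], si]
      if (t == 0L) return(invisible())
      ts <- mix$bcomp[amol[pp], si]
      if (mix$typ[t] != cp$typ[p]) return(invisible())
      if (!is.null(restrict) && !t %in% alive) return(invisible())
      if (t %in% amol[amol > 0L]) return(invisible())
      if (!is.na(cp$compart[p]) && mix$compart[t] != cp$compart[p]) return(invisible())
      forced <- setNames(list(ts), as.character(cj))
      for (as_ in enum_mention_assignments(cp, p, mix, t, forced)) {
        amol[p] <<- t; aslot[[p]] <<- as_
        rec(step + 1L)
      }
      amol[p] <<- 0L
    }
    invisible()
  }
  rec(1L)
  res
}

#' Enumerate embeddings of a pattern into a concrete target
#'
#' Returns every structure-preserving injective map of the pattern molecules
#' and component mentions into the target, including symmetric duplicates
#' (automorphic images count separately; rate laws divide by the symmetry
#' factor instead).
#'
#' @param pattern a pattern [site_graph()] or pattern string.
#' @param target a concrete species [site_graph()] or string (or a list of
#'   them, treated as a mixture of one copy each).
#' @param model an [rb_model()] declaring the molecule types.
#' @return list of embeddings; each has `mol` (target molecule index per
#'   pattern molecule) and `slot` (per pattern molecule, the target component
#'   slot matched by each component mention).
#' @export
find_embeddings <- function(pattern, target, model) {
  reg <- compile_registry(model)
  if (is.character(pattern)) pattern <- parse_pattern(pattern)
  cp <- compile_pattern(pattern, reg)
  if (!inherits(target, "site_graph") && !is.character(target)) {
    # list of species: concatenate into one mixture
    sgs <- lapply(target, function(x) if (is.character(x)) parse_pattern(x) else x)
    css <- lapply(sgs, compile_species, reg = reg, require_connected = FALSE)
    mix <- bind_species(css)
  } else {
    if (is.character(target)) target <- parse_pattern(target)
    mix <- species_as_mixture(compile_species(target, reg,
                                              require_connected = FALSE))
  }
  embs <- match_pattern(cp, mix)
  ord <- order(vapply(embs, function(e) paste(sprintf("%06d", e$mol), collapse = ""),
                      character(1)))
  embs[ord]
}

bind_species <- function(css) {
  offs <- cumsum(c(0L, vapply(css, `[[`, integer(1), "k")))
  typ <- unlist(lapply(css, `[[`, "typ"))
  st <- do.call(rbind, lapply(css, `[[`, "st"))
  compart <- unlist(lapply(css, `[[`, "compart"))
  bmol <- do.call(rbind, lapply(seq_along(css), function(i) {
    b <- css[[i]]$bmol
    b[b > 0L] <- b[b > 0L] + offs[i]
    b
  }))
  bcomp <- do.call(rbind, lapply(css, `[[`, "bcomp"))
  list(typ = typ, st = st, bmol = bmol, bcomp = bcomp, compart = compart)
}

# --- exact pattern isomorphism ----------------------------------------------

# Count structure- and annotation-preserving bijections from pattern A to
# pattern B (wildcards must map to identical wildcards). Used for symmetry
# factors and for deciding whether two reactant patterns are "the same".
pattern_iso_count <- function(cpA, cpB, count_all = TRUE) {
  if (cpA$k != cpB$k) return(0L)
  k <- cpA$k
  nb_index <- function(cp) {
    # per (mol, mention): bond row or 0
    idx <- lapply(seq_len(cp$k), function(i)
      integer(length(cp$men[[i]])))
    if (nrow(cp$bonds)) for (r in seq_len(nrow(cp$bonds))) {
      b <- cp$bonds[r, ]
      idx[[b[1]]][b[2]] <- r
      idx[[b[3]]][b[4]] <- r
    }
    idx
  }
  nbA <- nb_index(cpA); nbB <- nb_index(cpB)
  count <- 0L
  amol <- integer(k)        # A molecule -> B molecule
  amen <- vector("list", k) # A mention -> B mention
  usedB <- logical(k)

  men_sig <- function(cp, i, j) {
    m <- cp$men[[i]]
    mm <- m[[j]]
    paste(mm$name, mm$state_label %||% "NA", mm$kind, sep = "\r")
  }

  ok_bonds <- function() {
    # every A bond must map to a B bond with matching endpoints, and counts equal
    if (nrow(cpA$bonds) != nrow(cpB$bonds)) return(FALSE)
    if (nrow(cpA$bonds)) for (r in seq_len(nrow(cpA$bonds))) {
      b <- cpA$bonds[r, ]
      bi <- amol[b[1]]; bci <- amen[[b[1]]][b[2]]
      bj <- amol[b[3]]; bcj <- amen[[b[3]]][b[4]]
      rB <- nbB[[bi]][bci]
      if (rB == 0L) return(FALSE)
      bb <- cpB$bonds[rB, ]
      okf <- (bb[1] == bi && bb[2] == bci && bb[3] == bj && bb[4] == bcj)
      okr <- (bb[3] == bi && bb[4] == bci && bb[1] == bj && bb[2] == bcj)
      if (!okf && !okr) return(FALSE)
    }
    TRUE
  }

  rec <- function(i) {
    if (i > k) {
      if (ok_bonds()) count <<- count + 1L
      return(invisible())
    }
    for (t in seq_len(k)) {
      if (usedB[t]) next
      if (cpB$typ[t] != cpA$typ[i]) next
      ca <- cpA$compart[i]; cb <- cpB$compart[t]
      if (!identical(is.na(ca), is.na(cb)) || (!is.na(ca) && ca != cb)) next
      mA <- cpA$men[[i]]; mB <- cpB$men[[t]]
      if (length(mA) != length(mB)) next
      # enumerate mention bijections preserving signatures
      nmen <- length(mA)
      sigA <- vapply(seq_len(nmen), function(j) men_sig(cpA, i, j), character(1))
      sigB <- vapply(seq_len(nmen), function(j) men_sig(cpB, t, j), character(1))
      assigns <- list()
      cur <- integer(nmen)
      rec2 <- function(j, used) {
        if (j > nmen) { assigns[[length(assigns) + 1L]] <<- cur[seq_len(nmen)]; return(invisible()) }
        for (q in seq_len(nmen)) {
          if (q %in% used) next
          if (sigA[j] != sigB[q]) next
          cur[j] <<- q
          rec2(j + 1L, c(used, q))
        }
        invisible()
      }
      rec2(1L, integer(0))
      for (as_ in assigns) {
        amol[i] <<- t; amen[[i]] <<- as_; usedB[t] <<- TRUE
        rec(i + 1L)
        usedB[t] <<- FALSE
        if (!count_all && count > 0L) return(invisible())
      }
    }
    amol[i] <<- 0L
    invisible()
  }
  rec(1L)
  count
}

#' Count automorphisms of a pattern
#'
#' The number of annotation-preserving maps of a pattern onto itself. Used
#' as the mass-action symmetry factor so that, e.g., an `A + A` dimerization
#' rule is not double-counted.
#'
#' @param pattern pattern [site_graph()] or string.
#' @param model an [rb_model()] declaring the molecule types.
#' @return positive integer.
#' @export
count_automorphisms <- function(pattern, model) {
  reg <- compile_registry(model)
  if (is.character(pattern)) pattern <- parse_pattern(pattern)
  cp <- compile_pattern(pattern, reg)
  pattern_iso_count(cp, cp)
}

# Symmetry factor of a full reactant side (list of compiled patterns):
# product of per-pattern automorphisms, doubled when a 2-reactant rule has
# two isomorphic patterns (pattern-swap symmetry).
reactant_symmetry <- function(cps) {
  if (length(cps) == 0L) return(1L)
  f <- prod(vapply(cps, function(cp) pattern_iso_count(cp, cp), integer(1)))
  if (length(cps) == 2L && pattern_iso_count(cps[[1]], cps[[2]], count_all = FALSE) > 0L) {
    f <- f * 2L
  }
  f
}

# --- connectivity ------------------------------------------------------------

#' Split a site graph into connected components
#'
#' @param g a [site_graph()] (concrete or pattern).
#' @return list of `site_graph`s; molecule order within each component is
#'   preserved.
#' @export
connected_components <- function(g) {
  k <- length(g$mols)
  if (k == 0L) return(list())
  # union-find over molecules via shared bond labels
  parent <- seq_len(k)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  ends <- list()
  for (i in seq_len(k)) for (cc in g$mols[[i]]$comps) {
    if (!cc$bond %in% c("0", "+", "?")) ends[[cc$bond]] <- c(ends[[cc$bond]], i)
  }
  for (e in ends) {
    ra <- find(e[[1]]); rb <- find(e[[2]])
    if (ra != rb) parent[ra] <- rb
  }
  roots <- vapply(seq_len(k), find, integer(1))
  lapply(unique(roots), function(r) {
    structure(list(mols = g$mols[roots == r]), class = "site_graph")
  })
}
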