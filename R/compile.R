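# Compilation of user-level models, patterns and species into the indexed
# form used by the matcher and the simulators.
#
# A registry ("reg") indexes molecule types and their component slots. A
# mixture is a set of parallel arrays over molecule instances:
#   typ      integer type id per molecule (0 = dead slot)
#   st       n x maxC integer matrix of state codes (0 = stateless component)
#   bmol     n x maxC integer matrix: bonded partner molecule (0 = unbound)
#   bcomp    n x maxC integer matrix: bonded partner component slot
#   compart  character compartment tag per molecule
# State codes index the ordered state-label list of the owning component.

compile_registry <- function(model) {
  tnames <- names(model$molecule_types)
  types <- lapply(model$molecule_types, function(mt) {
    list(name = mt$name,
         comp_names = vapply(mt$comps, `[[`, character(1), "name"),
         comp_states = lapply(mt$comps, `[[`, "states"),
         home = mt$compartment)
  })
  maxC <- max(c(1L, vapply(types, function(t) length(t$comp_names), integer(1))))
  list(types = types,
       type_index = setNames(seq_along(tnames), tnames),
       maxC = maxC)
}

state_code <- function(reg, tid, slot, label) {
  labs <- reg$types[[tid]]$comp_states[[slot]]
  i <- match(label, labs)
  if (is.na(i)) stop("unknown state '", label, "' for component ",
                     reg$types[[tid]]$comp_names[slot], " of type ",
                     reg$types[[tid]]$name)
  i
}

state_label <- function(reg, tid, slot, code) {
  if (code == 0L) return(NA_character_)
  reg$types[[tid]]$comp_states[[slot]][code]
}

# --- pattern compilation -----------------------------------------------------

# Compiled pattern fields:
#   k        number of molecules
#   typ      integer type ids
#   compart  per-molecule compartment constraint (NA = unconstrained)
#   men      per molecule, a list of mentions:
#              name, cand (candidate slots), state_label (NA = wildcard),
#              st_code (per-candidate state code, NA if wildcard),
#              kind ("0","+","?","b"), bond (label for kind "b")
#   bonds    matrix (mi, ci, mj, cj): endpoints as (molecule, mention index)
#   plan     molecule visit order; per visited molecule the entry bond row
#            (0 = search root)
compile_pattern <- function(sg, reg) {
  k <- length(sg$mols)
  if (k == 0L) {
    return(list(k = 0L, typ = integer(0), compart = character(0),
                men = list(), bonds = matrix(0L, 0, 4), plan = NULL))
  }
  typ <- integer(k)
  compart <- character(k)
  men <- vector("list", k)
  ends <- list()  # bond label -> list of c(mol, mention)
  for (i in seq_len(k)) {
    m <- sg$mols[[i]]
    tid <- reg$type_index[[m$type]]
    if (is.null(tid) || is.na(tid)) stop("undeclared molecule type: ", m$type)
    typ[i] <- tid
    compart[i] <- m$compartment
    cn <- reg$types[[tid]]$comp_names
    men[[i]] <- lapply(seq_along(m$comps), function(j) {
      cc <- m$comps[[j]]
      cand <- which(cn == cc$name)
      if (!length(cand)) stop("type ", m$type, " has no component ", cc$name)
      st_code <- rep(NA_integer_, length(cand))
      if (!is.na(cc$state)) {
        keep <- logical(length(cand))
        for (q in seq_along(cand)) {
          labs <- reg$types[[tid]]$comp_states[[cand[q]]]
          w <- match(cc$state, labs)
          if (!is.na(w)) { keep[q] <- TRUE; st_code[q] <- w }
        }
        cand <- cand[keep]; st_code <- st_code[keep]
        if (!length(cand)) stop("no component ", cc$name, " of type ", m$type,
                                " admits state ", cc$state)
      }
      kind <- if (cc$bond %in% c("0", "+", "?")) cc$bond else "b"
      list(name = cc$name, cand = cand, state_label = cc$state,
           st_code = st_code, kind = kind, bond = cc$bond)
    })
    for (j in seq_along(m$comps)) {
      b <- m$comps[[j]]$bond
      if (!b %in% c("0", "+", "?")) {
        ends[[b]] <- c(ends[[b]], list(c(i, j)))
      }
    }
  }
  bonds <- if (length(ends)) {
    do.call(rbind, lapply(ends, function(e) c(e[[1]], e[[2]])))
  } else matrix(0L, 0, 4)
  storage.mode(bonds) <- "integer"
  cp <- list(k = k, typ = typ, compart = compart, men = men, bonds = bonds)
  cp$plan <- pattern_plan(cp)
  cp
}

# Breadth-first visit plan; disconnected patterns get one root per component.
pattern_plan <- function(cp) {
  k <- cp$k
  order <- integer(0)
  entry <- integer(0)   # bond row used to reach the molecule (0 = root)
  seen <- logical(k)
  nb <- cp$bonds
  repeat {
    root <- which(!seen)[1]
    if (is.na(root)) break
    seen[root] <- TRUE
    order <- c(order, root); entry <- c(entry, 0L)
    queue <- root
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      if (nrow(nb)) for (r in seq_len(nrow(nb))) {
        a <- nb[r, 1]; b <- nb[r, 3]
        nxt <- if (a == cur && !seen[b]) b else if (b == cur && !seen[a]) a else 0L
        if (nxt > 0L) {
          seen[nxt] <- TRUE
          order <- c(order, nxt); entry <- c(entry, r)
          queue <- c(queue, nxt)
        }
      }
    }
  }
  list(order = order, entry = entry,
       n_components = sum(entry == 0L))
}

pattern_connected <- function(cp) is.null(cp$plan) || cp$plan$n_components <= 1L

# --- species compilation -----------------------------------------------------

# Compile a concrete species graph: every component of the type must be
# mentioned exactly once (by name, in occurrence order), all states concrete,
# no wildcard bonds.
compile_species <- function(sg, reg, require_connected = TRUE) {
  k <- length(sg$mols)
  typ <- integer(k)
  st <- matrix(0L, k, reg$maxC)
  bmol <- matrix(0L, k, reg$maxC)
  bcomp <- matrix(0L, k, reg$maxC)
  compart <- character(k)
  ends <- list()
  for (i in seq_len(k)) {
    m <- sg$mols[[i]]
    tid <- reg$type_index[[m$type]]
    if (is.null(tid) || is.na(tid)) stop("undeclared molecule type: ", m$type)
    typ[i] <- tid
    tinfo <- reg$types[[tid]]
    compart[i] <- if (is.na(m$compartment)) tinfo$home else m$compartment
    cn <- tinfo$comp_names
    if (length(m$comps) != length(cn)) {
      stop("species molecule ", m$type, " must mention all ", length(cn),
           " components (got ", length(m$comps), ")")
    }
    taken <- logical(length(cn))
    for (j in seq_along(m$comps)) {
      cc <- m$comps[[j]]
      slot <- which(cn == cc$name & !taken)[1]
      if (is.na(slot)) stop("species molecule ", m$type,
                            ": unmatched component mention ", cc$name)
      taken[slot] <- TRUE
      labs <- tinfo$comp_states[[slot]]
      if (length(labs)) {
        if (is.na(cc$state)) stop("species molecule ", m$type, " component ",
                                  cc$name, " must have a concrete state")
        st[i, slot] <- state_code(reg, tid, slot, cc$state)
      } else if (!is.na(cc$state)) {
        stop("component ", cc$name, " of ", m$type, " is stateless")
      }
      if (cc$bond %in% c("+", "?")) {
        stop("concrete species cannot carry wildcard bonds")
      }
      if (cc$bond != "0") {
        ends[[cc$bond]] <- c(ends[[cc$bond]], list(c(i, slot)))
      }
    }
  }
  for (e in ends) {
    if (length(e) != 2L) stop("bond label not shared by exactly two endpoints")
    bmol[e[[1]][1], e[[1]][2]] <- e[[2]][1]
    bcomp[e[[1]][1], e[[1]][2]] <- e[[2]][2]
    bmol[e[[2]][1], e[[2]][2]] <- e[[1]][1]
    bcomp[e[[2]][1], e[[2]][2]] <- e[[1]][2]
  }
  if (require_connected && k > 1L && !mixture_connected(typ, bmol)) {
    stop("concrete species must be connected")
  }
  list(k = k, typ = typ, st = st, bmol = bmol, bcomp = bcomp, compart = compart)
}

mixture_connected <- function(typ, bmol) {
  k <- length(typ)
  seen <- logical(k)
  seen[1] <- TRUE
  queue <- 1L
  while (length(queue)) {
    cur <- queue[1]; queue <- queue[-1]
    nb <- bmol[cur, ]
    nb <- nb[!is.na(nb) & nb > 0L]
    for (x in nb) if (!seen[x]) { seen[x] <- TRUE; queue <- c(queue, x) }
  }
  all(seen)
}

# Wrap a compiled species (or several) as a standalone mixture target.
species_as_mixture <- function(cs) {
  list(typ = cs$typ, st = cs$st, bmol = cs$bmol, bcomp = cs$bcomp,
       compart = cs$compart)
}

# Convert a mixture subset back to a user-level site graph (molecule ids in
# `ids`, order preserved; bonds to molecules outside `ids` are an error).
mixture_to_sg <- function(mix, reg, ids) {
  idx <- setNames(seq_along(ids), as.character(ids))
  lab <- 0L
  pend <- new.env(parent = emptyenv())
  mols <- vector("list", length(ids))
  for (q in seq_along(ids)) {
    i <- ids[q]
    tid <- mix$typ[i]
    tinfo <- reg$types[[tid]]
    comps <- vector("list", length(tinfo$comp_names))
    for (s in seq_along(tinfo$comp_names)) {
      stl <- if (mix$st[i, s] > 0L) tinfo$comp_states[[s]][mix$st[i, s]] else NA_character_
      bond <- "0"
      pm <- mix$bmol[i, s]
      if (pm > 0L) {
        ps <- mix$bcomp[i, s]
        e <- rbind(c(i, s), c(pm, ps))
        e <- e[order(e[, 1], e[, 2]), , drop = FALSE]
        key <- paste(e[1, 1], e[1, 2], e[2, 1], e[2, 2], sep = ":")
        if (is.null(pend[[key]])) {
          lab <- lab + 1L
          pend[[key]] <- lab
        }
        if (is.null(idx[[as.character(pm)]])) {
          stop("bond leaves the requested molecule set")
        }
        bond <- as.character(pend[[key]])
      }
      comps[[s]] <- sg_comp(tinfo$comp_names[s], state = stl, bond = bond)
    }
    mm <- structure(list(type = tinfo$name, compartment = mix$compart[i],
                         comps = comps), class = "sg_mol")
    mols[[q]] <- mm
  }
  structure(list(mols = mols), class = "site_graph")
}
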