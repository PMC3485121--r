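# Operational diffs for rules: a rule is written reactants -> products, but
# the simulators need an explicit transformation list. Correspondence between
# reactant and product molecules is positional: within each type, occurrences
# are paired in order of appearance across the rule string. Extra reactant
# occurrences are deleted; extra product occurrences are created. Components
# are matched by (name, occurrence) within a molecule. Identical-molecule
# ambiguity (a swap of two indistinguishable molecules that changes the diff)
# is an error, never a guess.

tf <- function(kind, ...) structure(list(kind = kind, ...), class = "rb_transformation")

#' @export
format.rb_transformation <- function(x, ...) {
  ref_txt <- function(r) paste(r, collapse = ".")
  switch(x$kind,
         ChangeState = paste0("ChangeState(", ref_txt(x$ref), " -> ", x$state, ")"),
         AddBond = paste0("AddBond(", ref_txt(x$ref1), ", ", ref_txt(x$ref2), ")"),
         DeleteBond = paste0("DeleteBond(", ref_txt(x$ref1), ", ", ref_txt(x$ref2), ")"),
         DeleteMolecule = paste0("DeleteMolecule(", ref_txt(x$ref), ")"),
         CreateMolecule = paste0("CreateMolecule(", sg_to_text(site_graph(list(x$mol))), ")"),
         ChangeCompartment = paste0("ChangeCompartment(", ref_txt(x$ref), " -> ", x$compartment, ")"))
}

#' @export
print.rb_transformation <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

mol_signature <- function(m) {
  paste(m$type, m$compartment,
        paste(vapply(m$comps, function(cc)
          paste(cc$name, cc$state, cc$bond %in% c("0", "+", "?"), sep = "~"),
          character(1)), collapse = ","), sep = "|")
}

#' Derive the transformation list of a rule
#'
#' Computes the operational diff between the reactant and product patterns of
#' a rule under the positional correspondence convention. Applying the
#' returned transformations to the reactant side reproduces the product side
#' up to graph isomorphism (see [apply_transformations()]).
#'
#' @param reactants,products lists of pattern [site_graph()]s (or an
#'   [rb_rule()] passed as `reactants`, in which case `products` is ignored).
#' @return list of transformations. Reference triples are
#'   `(pattern index, molecule index, component mention index)` into the
#'   reactant side; created molecules are referenced as
#'   `("new", creation index, mention index)`.
#' @export
derive_transformations <- function(reactants, products = NULL) {
  if (inherits(reactants, "rb_rule")) {
    rule <- reactants
    reactants <- rule$reactants
    products <- rule$products
  }
  base <- diff_sides(reactants, products)
  # ambiguity check: permute identical product molecules and compare diffs
  pflat <- flatten_side(products)
  if (length(pflat)) {
    sigs <- vapply(pflat, function(x) mol_signature(x$m), character(1))
    for (s in unique(sigs[duplicated(sigs)])) {
      idxs <- which(sigs == s)
      if (length(idxs) < 2L) next
      for (a in idxs) for (b in idxs) {
        if (a >= b) next
        perm <- seq_along(pflat)
        perm[c(a, b)] <- perm[c(b, a)]
        alt <- tryCatch(diff_sides(reactants, products, pperm = perm),
                        error = function(e) NULL)
        if (is.null(alt) || !identical(tf_fingerprint(alt), tf_fingerprint(base))) {
          stop("ambiguous reactant/product correspondence: identical product ",
               "molecules admit different diffs", call. = FALSE)
        }
      }
    }
  }
  base
}

tf_fingerprint <- function(tfs) sort(vapply(tfs, format, character(1)))

flatten_side <- function(side) {
  out <- list()
  for (p in seq_along(side)) {
    for (j in seq_along(side[[p]]$mols)) {
      out[[length(out) + 1L]] <- list(pat = p, mol = j, m = side[[p]]$mols[[j]])
    }
  }
  out
}

diff_sides <- function(reactants, products, pperm = NULL) {
  rflat <- flatten_side(reactants)
  pflat <- flatten_side(products)
  if (!is.null(pperm)) pflat <- pflat[pperm]
  rtypes <- vapply(rflat, function(x) x$m$type, character(1))
  ptypes <- vapply(pflat, function(x) x$m$type, character(1))
  # positional pairing within type
  pair_r2p <- rep(NA_integer_, length(rflat))
  pair_p2r <- rep(NA_integer_, length(pflat))
  for (ty in unique(c(rtypes, ptypes))) {
    ri <- which(rtypes == ty); pi <- which(ptypes == ty)
    n <- min(length(ri), length(pi))
    if (n) { pair_r2p[ri[seq_len(n)]] <- pi[seq_len(n)]
             pair_p2r[pi[seq_len(n)]] <- ri[seq_len(n)] }
  }
  created <- which(is.na(pair_p2r))
  deleted <- which(is.na(pair_r2p))

  # mention keys: name + occurrence number
  mention_keys <- function(m) {
    nm <- vapply(m$comps, `[[`, character(1), "name")
    occ <- stats::ave(seq_along(nm), nm, FUN = seq_along)
    paste(nm, occ, sep = "#")
  }

  tfs <- list()
  add <- function(x) tfs[[length(tfs) + 1L]] <<- x

  # endpoint token: reactant mention or created-molecule mention
  r_token <- function(fi, mi) paste0("R:", rflat[[fi]]$pat, ":", rflat[[fi]]$mol, ":", mi)
  n_token <- function(ci, mi) paste0("N:", ci, ":", mi)
  r_ref <- function(fi, mi) c(rflat[[fi]]$pat, rflat[[fi]]$mol, mi)
  token_ref <- function(tok) {
    parts <- strsplit(tok, ":", fixed = TRUE)[[1]]
    if (parts[1] == "R") as.integer(parts[-1]) else c("new", parts[2], parts[3])
  }

  # creations (emitted first so AddBond can target them)
  for (q in seq_along(created)) {
    pm <- pflat[[created[q]]]$m
    for (cc in pm$comps) {
      if (cc$bond %in% c("+", "?")) {
        stop("created molecule cannot carry wildcard bonds", call. = FALSE)
      }
      if (is.na(cc$state)) next
    }
    add(tf("CreateMolecule", mol = pm, new_index = q))
  }

  # per-pair component diffs
  for (fi in seq_along(rflat)) {
    pi <- pair_r2p[fi]
    if (is.na(pi)) next
    rm_ <- rflat[[fi]]$m; pm_ <- pflat[[pi]]$m
    rkeys <- mention_keys(rm_); pkeys <- mention_keys(pm_)
    for (mi in seq_along(rm_$comps)) {
      pj <- match(rkeys[mi], pkeys)
      if (is.na(pj)) next  # component dropped on product side: unchanged
      rs <- rm_$comps[[mi]]$state; ps <- pm_$comps[[pj]]$state
      if (!is.na(ps) && (is.na(rs) || rs != ps)) {
        add(tf("ChangeState", ref = r_ref(fi, mi), state = ps))
      }
    }
    rc <- rm_$compartment; pc <- pm_$compartment
    if (!is.na(pc) && (is.na(rc) || rc != pc)) {
      add(tf("ChangeCompartment", ref = c(rflat[[fi]]$pat, rflat[[fi]]$mol),
             compartment = pc))
    }
  }

  # bond sets as unordered token pairs
  side_bonds <- function(flat, conserved_map, token_fun, created_index = NULL) {
    ends <- list()
    for (fi in seq_along(flat)) {
      m <- flat[[fi]]$m
      for (mi in seq_along(m$comps)) {
        b <- m$comps[[mi]]$bond
        if (b %in% c("0", "+", "?")) next
        key <- paste0(flat[[fi]]$pat, "/", b)
        ends[[key]] <- c(ends[[key]], list(token_fun(fi, mi)))
      }
    }
    pairs <- character(0)
    for (e in ends) {
      if (length(e) != 2L) stop("dangling bond label in rule pattern", call. = FALSE)
      pairs <- c(pairs, paste(sort(c(e[[1]], e[[2]])), collapse = "|"))
    }
    pairs
  }
  r_bonds <- side_bonds(rflat, token_fun = r_token)
  p_token <- function(fi, mi) {
    ri <- pair_p2r[fi]
    if (!is.na(ri)) {
      # translate product mention to reactant mention via (name, occurrence)
      keys_p <- mention_keys(pflat[[fi]]$m)
      keys_r <- mention_keys(rflat[[ri]]$m)
      mj <- match(keys_p[mi], keys_r)
      if (is.na(mj)) stop("product bond on a component absent from the reactant pattern",
                          call. = FALSE)
      r_token(ri, mj)
    } else {
      n_token(match(fi, created), mi)
    }
  }
  p_bonds <- side_bonds(pflat, token_fun = p_token)

  for (bp in setdiff(r_bonds, p_bonds)) {
    toks <- strsplit(bp, "|", fixed = TRUE)[[1]]
    add(tf("DeleteBond", ref1 = token_ref(toks[1]), ref2 = token_ref(toks[2])))
  }
  for (bp in setdiff(p_bonds, r_bonds)) {
    toks <- strsplit(bp, "|", fixed = TRUE)[[1]]
    add(tf("AddBond", ref1 = token_ref(toks[1]), ref2 = token_ref(toks[2])))
  }
  for (fi in deleted) {
    add(tf("DeleteMolecule", ref = c(rflat[[fi]]$pat, rflat[[fi]]$mol)))
  }
  if (!length(tfs)) stop("rule has no effect (empty transformation list)", call. = FALSE)
  tfs
}

#' Apply a transformation list to reactant patterns
#'
#' Applies the diff under the identity embedding and returns the resulting
#' connected components. Used to verify the round-trip property of
#' [derive_transformations()] and by the on-the-fly simulator to construct
#' product species.
#'
#' @param reactants list of [site_graph()]s.
#' @param transformations result of [derive_transformations()].
#' @return list of [site_graph()]s (connected components of the result).
#' @export
apply_transformations <- function(reactants, transformations) {
  mols <- list()          # working molecules
  key <- function(pat, mol) paste0(pat, ":", mol)
  index <- new.env(parent = emptyenv())
  for (p in seq_along(reactants)) {
    for (j in seq_along(reactants[[p]]$mols)) {
      m <- reactants[[p]]$mols[[j]]
      # re-label bonds so patterns do not collide
      m$comps <- lapply(m$comps, function(cc) {
        if (!cc$bond %in% c("0", "+", "?")) cc$bond <- paste0(p, "_", cc$bond)
        cc
      })
      mols[[length(mols) + 1L]] <- m
      index[[key(p, j)]] <- length(mols)
    }
  }
  new_base <- length(mols)
  deleted <- logical(0)
  next_label <- 1000L
  resolve <- function(ref) {
    if (identical(ref[1], "new")) {
      list(idx = new_base + as.integer(ref[2]), mention = as.integer(ref[3]))
    } else {
      ref <- as.integer(ref)
      list(idx = index[[key(ref[1], ref[2])]], mention = ref[3])
    }
  }
  for (t in transformations) {
    switch(t$kind,
      CreateMolecule = {
        mols[[length(mols) + 1L]] <- t$mol
      },
      ChangeState = {
        r <- resolve(t$ref)
        mols[[r$idx]]$comps[[r$mention]]$state <- t$state
      },
      ChangeCompartment = {
        r <- resolve(t$ref)
        mols[[r$idx]]$compartment <- t$compartment
      },
      AddBond = {
        r1 <- resolve(t$ref1); r2 <- resolve(t$ref2)
        next_label <- next_label + 1L
        lab <- paste0("nb", next_label)
        mols[[r1$idx]]$comps[[r1$mention]]$bond <- lab
        mols[[r2$idx]]$comps[[r2$mention]]$bond <- lab
      },
      DeleteBond = {
        r1 <- resolve(t$ref1); r2 <- resolve(t$ref2)
        mols[[r1$idx]]$comps[[r1$mention]]$bond <- "0"
        mols[[r2$idx]]$comps[[r2$mention]]$bond <- "0"
      },
      DeleteMolecule = {
        r <- as.integer(t$ref)
        idx <- index[[key(r[1], r[2])]]
        # sever remaining explicit bonds
        labs <- vapply(mols[[idx]]$comps, function(cc) cc$bond, character(1))
        labs <- labs[!labs %in% c("0", "+", "?")]
        for (q in seq_along(mols)) {
          if (q == idx) next
          mols[[q]]$comps <- lapply(mols[[q]]$comps, function(cc) {
            if (cc$bond %in% labs) cc$bond <- "0"
            cc
          })
        }
        deleted <- c(deleted, idx)
      })
    if (t$kind == "DeleteMolecule") deleted <- unique(deleted)
  }
  keep <- setdiff(seq_along(mols), deleted)
  if (!length(keep)) return(list())
  g <- structure(list(mols = mols[keep]), class = "site_graph")
  connected_components(g)
}
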