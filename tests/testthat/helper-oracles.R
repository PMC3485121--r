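# Independent oracles and random-instance generators shared by the tests.
# These deliberately avoid the package's matching/canonicalization code
# paths: the embedding oracle enumerates all injective maps by brute force
# at the user level, and the isomorphism oracle is defined through it.

# fixed small registry used by the matcher property tests; type A carries
# two interchangeable components named "x" to exercise duplicate-site
# symmetry
oracle_types_model <- function() {
  rb_model(
    molecule_types = list(
      molecule_type("A", "x", "x", "y~U~P"),
      molecule_type("B", "a", "b~U~P"),
      molecule_type("C", "c")),
    parameters = list())
}

# --- brute-force embedding enumeration --------------------------------------

# bond endpoint table of a user-level site graph: label -> list of (mol, comp)
sg_bond_ends <- function(g) {
  ends <- list()
  for (i in seq_along(g$mols)) {
    comps <- g$mols[[i]]$comps
    for (j in seq_along(comps)) {
      b <- comps[[j]]$bond
      if (!b %in% c("0", "+", "?")) ends[[b]] <- c(ends[[b]], list(c(i, j)))
    }
  }
  ends
}

# partner of target mention (i,j), or NULL
sg_partner <- function(ends, i, j) {
  for (e in ends) {
    if (identical(e[[1]], c(i, j))) return(e[[2]])
    if (identical(e[[2]], c(i, j))) return(e[[1]])
  }
  NULL
}

perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  out
}

# all embeddings of pattern into target (concrete), counted with component
# mention assignments, by exhaustive search over injective molecule maps and
# per-molecule mention permutations
oracle_embedding_count <- function(pattern, target) {
  pm <- pattern$mols; tm <- target$mols
  np <- length(pm); nt <- length(tm)
  if (np == 0L) return(0L)
  pends <- sg_bond_ends(pattern)
  tends <- sg_bond_ends(target)
  count <- 0L
  # injective maps pattern mol -> target mol
  mol_maps <- list()
  gen <- function(i, used, cur) {
    if (i > np) { mol_maps[[length(mol_maps) + 1L]] <<- cur; return(invisible()) }
    for (t in seq_len(nt)) {
      if (t %in% used) next
      if (tm[[t]]$type != pm[[i]]$type) next
      gen(i + 1L, c(used, t), c(cur, t))
    }
    invisible()
  }
  gen(1L, integer(0), integer(0))
  for (mp in mol_maps) {
    # per-molecule: all assignments of pattern mentions to target mentions
    per_mol <- lapply(seq_len(np), function(i) {
      pc <- pm[[i]]$comps; tc <- tm[[mp[i]]]$comps
      res <- list()
      nm <- length(pc)
      if (nm == 0L) return(list(integer(0)))
      assign_rec <- function(j, used, cur) {
        if (j > nm) { res[[length(res) + 1L]] <<- cur; return(invisible()) }
        for (q in seq_along(tc)) {
          if (q %in% used) next
          if (tc[[q]]$name != pc[[j]]$name) next
          if (!is.na(pc[[j]]$state) &&
              (is.na(tc[[q]]$state) || tc[[q]]$state != pc[[j]]$state)) next
          tb <- tc[[q]]$bond
          ok <- switch(pc[[j]]$bond,
                       "0" = tb == "0",
                       "+" = !tb %in% c("0", "+", "?"),
                       "?" = TRUE,
                       !tb %in% c("0", "+", "?"))  # explicit label
          if (!ok) next
          assign_rec(j + 1L, c(used, q), c(cur, q))
        }
        invisible()
      }
      assign_rec(1L, integer(0), integer(0))
      res
    })
    # cartesian product over molecules; then global bond check
    idx <- rep(1L, np)
    sizes <- vapply(per_mol, length, integer(1))
    if (any(sizes == 0L)) next
    repeat {
      asg <- lapply(seq_len(np), function(i) per_mol[[i]][[idx[i]]])
      ok <- TRUE
      for (e in pends) {
        p1 <- e[[1]]; p2 <- e[[2]]
        t1 <- c(mp[p1[1]], asg[[p1[1]]][p1[2]])
        t2 <- c(mp[p2[1]], asg[[p2[1]]][p2[2]])
        pr <- sg_partner(tends, t1[1], t1[2])
        if (is.null(pr) || !identical(pr, t2)) { ok <- FALSE; break }
      }
      if (ok) count <- count + 1L
      # advance
      k <- 1L
      while (k <= np) {
        idx[k] <- idx[k] + 1L
        if (idx[k] <= sizes[k]) break
        idx[k] <- 1L; k <- k + 1L
      }
      if (k > np) break
    }
  }
  count
}

# isomorphism of two concrete species via the embedding oracle
oracle_isomorphic <- function(s1, s2) {
  if (length(s1$mols) != length(s2$mols)) return(FALSE)
  oracle_embedding_count(s1, s2) > 0L
}

# --- random instances --------------------------------------------------------

random_species_sg <- function(n_mol, model = oracle_types_model(),
                              p_bond = 0.6) {
  tdefs <- model$molecule_types
  mols <- lapply(seq_len(n_mol), function(i) {
    mt <- tdefs[[sample.int(length(tdefs), 1L)]]
    comps <- lapply(mt$comps, function(cc) {
      st <- if (length(cc$states)) sample(cc$states, 1L) else NA_character_
      sg_comp(cc$name, state = st, bond = "0")
    })
    structure(list(type = mt$name, compartment = NA_character_,
                   comps = comps), class = "sg_mol")
  })
  # random bonds between free mentions
  free <- do.call(rbind, lapply(seq_along(mols), function(i)
    cbind(i, seq_along(mols[[i]]$comps))))
  free <- free[sample.int(nrow(free)), , drop = FALSE]
  lab <- 0L
  while (nrow(free) >= 2L && runif(1) < p_bond) {
    lab <- lab + 1L
    a <- free[1, ]; b <- free[2, ]
    mols[[a[1]]]$comps[[a[2]]]$bond <- as.character(lab)
    mols[[b[1]]]$comps[[b[2]]]$bond <- as.character(lab)
    free <- free[-(1:2), , drop = FALSE]
  }
  structure(list(mols = mols), class = "site_graph")
}

# a random connected pattern over the same registry
random_pattern_sg <- function(n_mol, model = oracle_types_model()) {
  tdefs <- model$molecule_types
  mols <- lapply(seq_len(n_mol), function(i) {
    mt <- tdefs[[sample.int(length(tdefs), 1L)]]
    keep <- which(runif(length(mt$comps)) < 0.8)
    comps <- lapply(mt$comps[keep], function(cc) {
      st <- if (length(cc$states) && runif(1) < 0.5) sample(cc$states, 1L) else NA_character_
      bond <- sample(c("0", "+", "?"), 1L, prob = c(0.55, 0.25, 0.2))
      sg_comp(cc$name, state = st, bond = bond)
    })
    structure(list(type = mt$name, compartment = NA_character_,
                   comps = comps), class = "sg_mol")
  })
  # connect molecules 2..n to an earlier one through explicit bonds
  lab <- 100L
  if (n_mol > 1L) for (i in 2:n_mol) {
    j <- sample.int(i - 1L, 1L)
    if (!length(mols[[i]]$comps) || !length(mols[[j]]$comps)) return(NULL)
    ci <- sample.int(length(mols[[i]]$comps), 1L)
    cj <- sample.int(length(mols[[j]]$comps), 1L)
    if (!mols[[i]]$comps[[ci]]$bond %in% c("0", "+", "?") ||
        !mols[[j]]$comps[[cj]]$bond %in% c("0", "+", "?")) return(NULL)
    lab <- lab + 1L
    mols[[i]]$comps[[ci]]$bond <- as.character(lab)
    mols[[j]]$comps[[cj]]$bond <- as.character(lab)
  }
  structure(list(mols = mols), class = "site_graph")
}

# relabel/permute a species into an isomorphic copy
shuffled_copy <- function(s) {
  ord <- sample(seq_along(s$mols))
  g <- structure(list(mols = s$mols[ord]), class = "site_graph")
  # bond labels are preserved by construction; renumber them
  ends <- sg_bond_ends(g)
  relab <- setNames(as.character(sample(1000 + seq_along(ends))), names(ends))
  for (i in seq_along(g$mols)) {
    for (j in seq_along(g$mols[[i]]$comps)) {
      b <- g$mols[[i]]$comps[[j]]$bond
      if (!b %in% c("0", "+", "?")) g$mols[[i]]$comps[[j]]$bond <- relab[[b]]
    }
  }
  g
}

# --- exact chemical master equation for the A+B<->AB toy ---------------------

# distribution of the complex count at time t, starting from k=0, for
# nA = nB = n: birth-death chain with birth kon*(n-k)^2, death koff*k
cme_binding_distribution <- function(n, kon, koff, t) {
  states <- 0:n
  Q <- matrix(0, n + 1L, n + 1L)
  for (k in states) {
    up <- if (k < n) kon * (n - k)^2 else 0
    down <- koff * k
    if (k < n) Q[k + 1L, k + 2L] <- up
    if (k > 0) Q[k + 1L, k] <- down
    Q[k + 1L, k + 1L] <- -(up + down)
  }
  P <- Matrix::expm(Matrix::Matrix(t * Q))
  as.numeric(P[1L, ])
}

# deterministic mass-action equilibrium of A+B<->AB
binding_equilibrium <- function(nA, nB, kon, koff) {
  # kon (nA - c)(nB - c) = koff c
  a <- kon; b <- -(kon * (nA + nB) + koff); cc <- kon * nA * nB
  (-b - sqrt(b^2 - 4 * a * cc)) / (2 * a)
}

# chi-squared goodness of fit with tail merging (expected >= 5)
chisq_gof <- function(observed_counts, probs, n_runs) {
  expected <- probs * n_runs
  # merge low-expectation bins from both tails
  keep <- expected >= 5
  if (!all(keep)) {
    lo <- which(!keep & seq_along(keep) < which.max(expected))
    hi <- which(!keep & seq_along(keep) > which.max(expected))
    o <- observed_counts; e <- expected
    obins <- c(if (length(lo)) sum(o[lo]), o[setdiff(which(keep), c(lo, hi))],
               if (length(hi)) sum(o[hi]))
    ebins <- c(if (length(lo)) sum(e[lo]), e[setdiff(which(keep), c(lo, hi))],
               if (length(hi)) sum(e[hi]))
  } else { obins <- observed_counts; ebins <- expected }
  ok <- ebins > 0
  x2 <- sum((obins[ok] - ebins[ok])^2 / ebins[ok])
  df <- sum(ok) - 1L
  stats::pchisq(x2, df, lower.tail = FALSE)
}
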