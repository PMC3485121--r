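# Population-based stochastic simulation with lazy (on-the-fly) reaction
# network generation: species and reactions are materialized only when a
# species first becomes populated. The cost therefore grows with the size of
# the *populated* part of the implied network, which on combinatorially
# complex models explodes with simulated time; this simulator exists both as
# an independent oracle for the network-free engine and to exhibit that
# contrast. Direct-method SSA with a linear propensity scan.

otf_new_network <- function(model, crm, max_species = 50000L,
                            max_reactions = 10L * max_species) {
  net <- new.env(parent = emptyenv())
  net$model <- model
  net$reg <- crm$reg
  net$rules <- crm$rules
  net$obs <- crm$obs
  net$species <- list()       # compiled species
  net$labels <- character(0)
  net$label_index <- new.env(parent = emptyenv())
  net$pop <- numeric(0)
  net$ever_pop <- logical(0)
  net$expanded <- logical(0)
  net$obs_weight <- NULL      # species x observable matrix (Molecules counts)
  net$obs_hit <- NULL         # species x observable 0/1 (Species counts)
  net$r1 <- integer(0); net$r2 <- integer(0)
  net$c0 <- numeric(0)        # k * multiplicity / sym (unscaled)
  net$bimol <- logical(0)
  net$rule_id <- integer(0)
  net$prod <- list()
  net$chan_keys <- new.env(parent = emptyenv())
  net$emb_cache <- new.env(parent = emptyenv())  # per (rule,slot,species)
  net$slot_species <- new.env(parent = emptyenv())  # expanded species per slot
  net$max_species <- as.integer(max_species)
  net$max_reactions <- as.integer(max_reactions)
  net$capped <- FALSE
  net
}

otf_add_species <- function(net, cs) {
  lab <- canonical_label_cs(cs, net$reg)
  if (!is.null(net$label_index[[lab]])) return(net$label_index[[lab]])
  if (length(net$species) >= net$max_species) {
    net$capped <- TRUE
    return(NA_integer_)
  }
  idx <- length(net$species) + 1L
  net$species[[idx]] <- cs
  net$labels[idx] <- lab
  net$label_index[[lab]] <- idx
  net$pop[idx] <- 0
  net$ever_pop[idx] <- FALSE
  net$expanded[idx] <- FALSE
  mixv <- species_as_mixture(cs)
  w <- vapply(net$obs, function(ob) {
    sum(vapply(ob$cps, function(cp) length(match_pattern(cp, mixv)), integer(1)))
  }, numeric(1))
  net$obs_weight <- rbind(net$obs_weight, w)
  net$obs_hit <- rbind(net$obs_hit, as.numeric(w > 0))
  idx
}

otf_embs <- function(net, r, s, si) {
  key <- paste(r, s, si, sep = "_")
  if (is.null(net$emb_cache[[key]])) {
    net$emb_cache[[key]] <- match_pattern(net$rules[[r]]$cps[[s]],
                                          species_as_mixture(net$species[[si]]))
  }
  net$emb_cache[[key]]
}

# slice a post-event mini-state into per-complex compiled species
state_complexes_to_cs <- function(st) {
  alive <- which(st$typ[seq_len(st$n)] > 0L)
  if (!length(alive)) return(list())
  lapply(split(alive, st$cmplx[alive]), function(ids) {
    remap <- setNames(seq_along(ids), ids)
    nc <- ncol(st$st)
    bm <- st$bmol[ids, , drop = FALSE]
    bm[bm > 0L] <- as.integer(remap[as.character(bm[bm > 0L])])
    list(k = length(ids), typ = st$typ[ids],
         st = st$st[ids, , drop = FALSE],
         bmol = bm, bcomp = st$bcomp[ids, , drop = FALSE],
         compart = st$compart[ids])
  })
}

# products of firing rule r on species combo (si[, sj]) with embeddings e1,e2
otf_products <- function(net, crm, r, sis, embs) {
  st <- nf_new_state(net$model, crm, cap = 64L, build_index = FALSE)
  offs <- integer(length(sis))
  for (q in seq_along(sis)) {
    offs[q] <- st$n
    nf_add_species(st, net$species[[sis[q]]], 1L)
  }
  chosen <- lapply(seq_along(embs), function(q) {
    e <- embs[[q]]
    list(mol = e$mol + offs[q], slot = e$slot)
  })
  nf_apply(st, r, chosen)
  state_complexes_to_cs(st)
}

# Enumerate all reaction channels obtained by firing rule r with reactant
# species si (slot assignments sis, one species per slot), and register them.
otf_register_channels <- function(net, crm, r, sis) {
  ru <- net$rules[[r]]
  emb_sets <- lapply(seq_along(sis), function(s) otf_embs(net, r, s, sis[s]))
  if (any(vapply(emb_sets, length, integer(1)) == 0L)) return(invisible())
  combos <- expand.grid(lapply(emb_sets, seq_along))
  for (ci in seq_len(nrow(combos))) {
    if (length(net$c0) >= net$max_reactions) { net$capped <- TRUE; break }
    embs <- lapply(seq_along(sis), function(s) emb_sets[[s]][[combos[ci, s]]])
    prods_cs <- otf_products(net, crm, r, sis, embs)
    pidx <- vapply(prods_cs, function(cs) otf_add_species(net, cs), integer(1))
    if (anyNA(pidx)) { net$capped <- TRUE; next }
    key <- paste(r, paste(sis, collapse = ","),
                 paste(sort(pidx), collapse = ","), sep = "|")
    if (!is.null(net$chan_keys[[key]])) {
      j <- net$chan_keys[[key]]
      net$c0[j] <- net$c0[j] + ru$k / ru$sym
    } else {
      j <- length(net$c0) + 1L
      net$chan_keys[[key]] <- j
      net$r1[j] <- sis[1]
      net$r2[j] <- if (length(sis) == 2L) sis[2] else 0L
      net$c0[j] <- ru$k / ru$sym
      net$bimol[j] <- length(sis) == 2L
      net$rule_id[j] <- r
      net$prod[[j]] <- pidx
    }
  }
  invisible()
}

#' Expand one frontier species of an on-the-fly network
#'
#' Generates every reaction whose reactants are all drawn from previously
#' expanded species plus this one; novel product species are canonicalized
#' and join the frontier. Idempotent per species.
#' @noRd
otf_expand_species <- function(net, crm, si) {
  if (net$expanded[si]) return(invisible())
  net$expanded[si] <- TRUE
  slot_key <- function(r, s) paste0(r, "_", s)
  for (r in seq_along(net$rules)) {
    ru <- net$rules[[r]]
    if (ru$nslots == 0L) next
    if (ru$nslots == 1L) {
      if (length(otf_embs(net, r, 1L, si))) {
        otf_register_channels(net, crm, r, si)
      }
    } else {
      has1 <- length(otf_embs(net, r, 1L, si)) > 0L
      has2 <- length(otf_embs(net, r, 2L, si)) > 0L
      # register this species as an available slot filler first so the
      # same-species pair (si, si) is generated exactly once below
      k1 <- slot_key(r, 1L); k2 <- slot_key(r, 2L)
      if (has1) net$slot_species[[k1]] <- c(net$slot_species[[k1]], si)
      if (has2) net$slot_species[[k2]] <- c(net$slot_species[[k2]], si)
      if (has1) {
        for (sj in net$slot_species[[k2]]) {
          otf_register_channels(net, crm, r, c(si, sj))
        }
      }
      if (has2) {
        for (sj in setdiff(net$slot_species[[k1]], si)) {
          otf_register_channels(net, crm, r, c(sj, si))
        }
      }
    }
  }
  invisible()
}

otf_propensities <- function(net, scale = 1) {
  if (!length(net$c0)) return(numeric(0))
  n1 <- net$pop[net$r1]
  a <- net$c0 * n1
  bi <- net$bimol
  if (any(bi)) {
    same <- bi & net$r1 == net$r2
    dif <- bi & !same
    a[dif] <- a[dif] * net$pop[net$r2[dif]] / scale
    a[same] <- a[same] * pmax(0, n1[same] - 1) / scale
  }
  a
}

otf_expand_populated <- function(net, crm) {
  repeat {
    if (net$capped) break
    todo <- which(net$pop > 0 & !net$expanded[seq_along(net$pop)])
    if (!length(todo)) break
    for (si in todo) otf_expand_species(net, crm, si)
  }
  invisible()
}

#' Run an on-the-fly (lazy network generation) stochastic simulation
#'
#' Gillespie direct-method simulation over the currently generated reaction
#' network; whenever a reaction populates a species still on the frontier,
#' that species is rule-expanded before the next step. Reaction rate
#' constants carry embedding multiplicity and symmetry factors matching
#' [simulate_network_free()], so the two simulators sample the same Markov
#' process.
#'
#' @inheritParams simulate_network_free
#' @param max_species cap on the number of generated species; reaching it
#'   stops network growth gracefully and flags the result as partial (on
#'   combinatorially complex models this is the expected outcome).
#' @param max_reactions companion cap on generated reaction channels.
#' @return list with elements `trajectory` (an `rb_trajectory`) and `census`
#'   (data frame: `time`, `populated_species` (population >= 1 at the sample
#'   instant), `ever_populated_species` (ever reached population >= 1; the
#'   monotone reading of a populated-species census),
#'   `total_species_generated`, `total_reactions_generated`).
#' @export
simulate_onthefly <- function(model, params = NULL, protocol = NULL,
                              t_end, sample_dt, seed, scale = 1,
                              max_species = 50000L,
                              max_reactions = 10L * max_species) {
  stopifnot(t_end > 0, sample_dt > 0)
  set.seed(seed)
  crm <- compile_run_model(model, params)
  net <- otf_new_network(model, crm, max_species, max_reactions)
  for (s in model$seed_species) {
    cs <- compile_species(s$species, crm$reg)
    si <- otf_add_species(net, cs)
    net$pop[si] <- net$pop[si] + round(seed_copy_number(s, model) * scale)
    net$ever_pop[si] <- net$pop[si] > 0
  }
  otf_expand_populated(net, crm)

  run_until <- function(t, t_stop) {
    repeat {
      a <- otf_propensities(net, scale)
      total <- sum(a)
      if (total <= 0) return(t_stop)
      dt <- rexp(1, total)
      if (t + dt > t_stop) return(t_stop)
      t <- t + dt
      j <- sample.int(length(a), 1L, prob = a)
      net$pop[net$r1[j]] <- net$pop[net$r1[j]] - 1
      if (net$r2[j] > 0L) net$pop[net$r2[j]] <- net$pop[net$r2[j]] - 1
      for (pi in net$prod[[j]]) {
        net$pop[pi] <- net$pop[pi] + 1
        net$ever_pop[pi] <- TRUE
      }
      otf_expand_populated(net, crm)
    }
  }

  t <- 0
  if (!is.null(protocol) && protocol$equilibrate > 0) {
    run_until(-protocol$equilibrate, 0)
  }
  if (!is.null(protocol)) {
    for (ad in protocol$additions) {
      sg <- if (is.character(ad$species)) parse_pattern(ad$species) else ad$species
      cs <- compile_species(sg, crm$reg)
      si <- otf_add_species(net, cs)
      if (is.na(si)) stop("species cap reached while applying protocol additions")
      net$pop[si] <- net$pop[si] + resolve_addition_copies(ad, model, scale)
      net$ever_pop[si] <- net$pop[si] > 0
    }
    otf_expand_populated(net, crm)
  }

  times <- seq(0, t_end, by = sample_dt)
  nobs <- length(crm$obs)
  values <- matrix(0, length(times), nobs)
  census <- data.frame(time = times, populated_species = 0L,
                       ever_populated_species = 0L,
                       total_species_generated = 0L,
                       total_reactions_generated = 0L)
  for (ti in seq_along(times)) {
    if (ti > 1L) t <- run_until(t, times[ti])
    if (nobs) {
      kindS <- vapply(crm$obs, function(o) o$kind == "Species", logical(1))
      w <- net$obs_weight
      w[, kindS] <- net$obs_hit[, kindS, drop = FALSE]
      values[ti, ] <- as.numeric(net$pop %*% w)
    }
    census$populated_species[ti] <- sum(net$pop > 0)
    census$ever_populated_species[ti] <- sum(net$ever_pop)
    census$total_species_generated[ti] <- length(net$species)
    census$total_reactions_generated[ti] <- length(net$c0)
  }
  obs_names <- vapply(crm$obs, `[[`, character(1), "name")
  colnames(values) <- obs_names
  traj <- structure(list(times = times, values = values,
                         observable_names = obs_names,
                         metadata = list(method = "onthefly", seed = seed,
                                         scale = scale,
                                         species_generated = length(net$species),
                                         reactions_generated = length(net$c0),
                                         capped = net$capped)),
                    class = "rb_trajectory")
  list(trajectory = traj, census = census, network = net)
}

#' Export an on-the-fly species census as CSV
#'
#' @param census census data frame from [simulate_onthefly()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_census <- function(census, path) {
  write.csv(census, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Dump a generated reaction network as JSON
#'
#' @param network `network` element of a [simulate_onthefly()] result.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path) {
  out <- list(
    species = data.frame(label = network$labels,
                         population = network$pop),
    reactions = data.frame(
      rule = vapply(network$rule_id, function(r) network$rules[[r]]$name, character(1)),
      reactant1 = network$labels[network$r1],
      reactant2 = ifelse(network$r2 > 0L, network$labels[pmax(network$r2, 1L)], ""),
      rate_constant = network$c0,
      products = vapply(network$prod, function(p)
        paste(network$labels[p], collapse = " + "), character(1))),
    capped = network$capped)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
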