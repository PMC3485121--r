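# Particle-based network-free stochastic simulator.
#
# Every molecule instance is tracked individually; rule firings are sampled
# from per-rule embedding counts, so the cost of an event depends on the
# number of particles, components and rules, never on the number of species
# or reactions the rules imply. Bimolecular selections whose embeddings fall
# in the same complex are null events (time advances, no change), which
# keeps the rejection-based algorithm exact while enforcing that 2-reactant
# rules describe inter-complex events.
#
# All stochastic choices are drawn from R's RNG in a fixed order (waiting
# time, rule, embedding(s)), so a run is bit-reproducible per seed.

# --- compiled run-time model -------------------------------------------------

compile_run_model <- function(model, params = NULL, reg = compile_registry(model)) {
  crules <- lapply(model$rules, function(r) {
    cps <- lapply(r$reactants, compile_pattern, reg = reg)
    for (cp in cps) {
      if (!pattern_connected(cp)) stop("rule ", r$name,
                                       ": reactant patterns must be connected")
    }
    tfs <- derive_transformations(r)
    list(name = r$name, cps = cps, tfs = tfs,
         sym = reactant_symmetry(cps),
         k = param_value(model, r$rate_param, params),
         nslots = length(cps))
  })
  cobs <- lapply(model$observables, function(ob) {
    list(name = ob$name, kind = ob$kind,
         cps = lapply(ob$patterns, compile_pattern, reg = reg))
  })
  list(reg = reg, rules = crules, obs = cobs)
}

# --- simulation state --------------------------------------------------------

nf_new_state <- function(model, crm, cap = 256L, build_index = TRUE) {
  st <- new.env(parent = emptyenv())
  st$model <- model
  st$reg <- crm$reg
  st$rules <- crm$rules
  st$obs <- crm$obs
  st$cap <- cap
  st$n <- 0L
  st$typ <- integer(cap)
  st$st <- matrix(0L, cap, crm$reg$maxC)
  st$bmol <- matrix(0L, cap, crm$reg$maxC)
  st$bcomp <- matrix(0L, cap, crm$reg$maxC)
  st$compart <- character(cap)
  st$cmplx <- integer(cap)
  st$members <- new.env(parent = emptyenv())
  st$next_cmplx <- 0L
  st$time <- 0
  st$event_count <- 0L
  st$null_count <- 0L
  st$work <- 0             # cumulative embedding updates (cost proxy)
  st$work_log <- NULL
  # entries: one per (rule slot) + one per (observable pattern)
  if (!build_index) {
    st$entries <- list()
    st$E <- list()
    st$entry_of_rule <- matrix(0L, length(crm$rules), 2L)
    st$entry_of_obs <- list()
    return(st)
  }
  entries <- list()
  for (r in seq_along(crm$rules)) {
    for (s in seq_len(crm$rules[[r]]$nslots)) {
      entries[[length(entries) + 1L]] <-
        list(cp = crm$rules[[r]]$cps[[s]], owner = c("rule", r, s))
    }
  }
  for (o in seq_along(crm$obs)) {
    for (s in seq_along(crm$obs[[o]]$cps)) {
      entries[[length(entries) + 1L]] <-
        list(cp = crm$obs[[o]]$cps[[s]], owner = c("obs", o, s))
    }
  }
  st$entries <- entries
  st$entry_of_rule <- matrix(0L, length(crm$rules), 2L)
  st$entry_of_obs <- lapply(seq_along(crm$obs), function(o) integer(0))
  for (j in seq_along(entries)) {
    ow <- entries[[j]]$owner
    if (ow[1] == "rule") {
      st$entry_of_rule[as.integer(ow[2]), as.integer(ow[3])] <- j
    } else {
      o <- as.integer(ow[2])
      st$entry_of_obs[[o]] <- c(st$entry_of_obs[[o]], j)
    }
  }
  st$E <- lapply(entries, function(e) list(mol = matrix(0L, e$cp$k, 0L),
                                           slot = list()))
  st
}

nf_grow <- function(st, need) {
  while (st$cap < need) {
    newcap <- st$cap * 2L
    st$typ <- c(st$typ, integer(st$cap))
    st$st <- rbind(st$st, matrix(0L, st$cap, ncol(st$st)))
    st$bmol <- rbind(st$bmol, matrix(0L, st$cap, ncol(st$bmol)))
    st$bcomp <- rbind(st$bcomp, matrix(0L, st$cap, ncol(st$bcomp)))
    st$compart <- c(st$compart, character(st$cap))
    st$cmplx <- c(st$cmplx, integer(st$cap))
    st$cap <- newcap
  }
}

# instantiate `copies` copies of compiled species cs; returns molecule ids
nf_add_species <- function(st, cs, copies) {
  copies <- as.integer(round(copies))
  if (copies <= 0L) return(invisible(integer(0)))
  k <- cs$k
  need <- st$n + copies * k
  nf_grow(st, need)
  base <- st$n
  rows <- rep(seq_len(k), copies)
  idx <- base + seq_len(copies * k)
  st$typ[idx] <- cs$typ[rows]
  st$st[idx, ] <- cs$st[rows, , drop = FALSE]
  st$compart[idx] <- cs$compart[rows]
  off <- base + rep((seq_len(copies) - 1L) * k, each = k)
  bm <- cs$bmol[rows, , drop = FALSE]
  bm[bm > 0L] <- bm[bm > 0L] + off[row(bm)[bm > 0L]]
  st$bmol[idx, ] <- bm
  st$bcomp[idx, ] <- cs$bcomp[rows, , drop = FALSE]
  cid0 <- st$next_cmplx
  st$cmplx[idx] <- cid0 + rep(seq_len(copies), each = k)
  for (cpy in seq_len(copies)) {
    st$members[[as.character(cid0 + cpy)]] <- base + (cpy - 1L) * k + seq_len(k)
  }
  st$next_cmplx <- cid0 + copies
  st$n <- max(st$n, need)
  invisible(idx)
}

# (re)build the full embedding index from scratch
nf_index_all <- function(st) {
  for (j in seq_along(st$entries)) {
    embs <- match_pattern(st$entries[[j]]$cp, st)
    st$E[[j]] <- pack_embs(st$entries[[j]]$cp, embs)
    st$work <- st$work + length(embs)
  }
  invisible(st)
}

pack_embs <- function(cp, embs) {
  if (!length(embs)) return(list(mol = matrix(0L, cp$k, 0L), slot = list()))
  list(mol = matrix(vapply(embs, `[[`, integer(cp$k), "mol"), nrow = cp$k),
       slot = lapply(embs, `[[`, "slot"))
}

entry_count <- function(st, j) ncol(st$E[[j]]$mol)

# --- rates -------------------------------------------------------------------

#' Total reaction rate of a network-free simulation state
#' @noRd
nf_rates <- function(st, scale = 1) {
  vapply(seq_along(st$rules), function(r) {
    ru <- st$rules[[r]]
    k <- ru$k
    if (ru$nslots == 2L) k <- k / scale
    if (ru$nslots == 0L) return(k)
    j1 <- st$entry_of_rule[r, 1]
    n1 <- entry_count(st, j1)
    if (ru$nslots == 1L) return(k * n1 / ru$sym)
    j2 <- st$entry_of_rule[r, 2]
    if (identical_entries(st, j1, j2)) {
      k * n1 * max(0L, n1 - 1L) / ru$sym
    } else {
      k * n1 * entry_count(st, j2) / ru$sym
    }
  }, numeric(1))
}

# two rule slots index "the same pattern" iff the patterns are isomorphic;
# cache the decision on first use
identical_entries <- function(st, j1, j2) {
  key <- paste0("same_", j1, "_", j2)
  if (!exists(key, envir = st, inherits = FALSE)) {
    v <- pattern_iso_count(st$entries[[j1]]$cp, st$entries[[j2]]$cp,
                           count_all = FALSE) > 0L
    assign(key, v, envir = st)
  }
  get(key, envir = st, inherits = FALSE)
}

# --- event application -------------------------------------------------------

# apply one rule firing given chosen embeddings (list per slot);
# returns affected molecule ids (post-event)
nf_apply <- function(st, r, chosen) {
  ru <- st$rules[[r]]
  reg <- st$reg
  # affected complexes (pre-event)
  mols0 <- unlist(lapply(chosen, function(e) e$mol))
  cids <- unique(st$cmplx[mols0])
  affected <- unlist(lapply(as.character(cids), function(k) st$members[[k]]))
  created <- integer(0)
  resolve <- function(ref) {
    if (identical(ref[1], "new")) {
      i <- created[as.integer(ref[2])]
      list(m = i, s = as.integer(ref[3]))
    } else {
      ref <- as.integer(ref)
      e <- chosen[[ref[1]]]
      list(m = e$mol[ref[2]], s = e$slot[[ref[2]]][ref[3]])
    }
  }
  for (t in ru$tfs) {
    switch(t$kind,
      CreateMolecule = {
        cs <- compile_species(site_graph(list(t$mol)), reg,
                              require_connected = FALSE)
        ids <- nf_add_species(st, cs, 1L)
        created <- c(created, ids)
        affected <- c(affected, ids)
      },
      ChangeState = {
        x <- resolve(t$ref)
        st$st[x$m, x$s] <- state_code(reg, st$typ[x$m], x$s, t$state)
      },
      ChangeCompartment = {
        x <- resolve(c(t$ref, 1L))
        st$compart[x$m] <- t$compartment
      },
      AddBond = {
        a <- resolve(t$ref1); b <- resolve(t$ref2)
        st$bmol[a$m, a$s] <- b$m; st$bcomp[a$m, a$s] <- b$s
        st$bmol[b$m, b$s] <- a$m; st$bcomp[b$m, b$s] <- a$s
        nf_merge_complexes(st, a$m, b$m)
      },
      DeleteBond = {
        a <- resolve(t$ref1); b <- resolve(t$ref2)
        st$bmol[a$m, a$s] <- 0L; st$bcomp[a$m, a$s] <- 0L
        st$bmol[b$m, b$s] <- 0L; st$bcomp[b$m, b$s] <- 0L
        nf_maybe_split(st, a$m, b$m)
      },
      DeleteMolecule = {
        ref <- as.integer(t$ref)
        m <- chosen[[ref[1]]]$mol[ref[2]]
        # sever all bonds, then retire the particle
        for (s in which(st$bmol[m, ] > 0L)) {
          pm <- st$bmol[m, s]; ps <- st$bcomp[m, s]
          st$bmol[pm, ps] <- 0L; st$bcomp[pm, ps] <- 0L
          st$bmol[m, s] <- 0L; st$bcomp[m, s] <- 0L
          nf_maybe_split(st, m, pm)
        }
        cid <- as.character(st$cmplx[m])
        st$members[[cid]] <- setdiff(st$members[[cid]], m)
        if (!length(st$members[[cid]])) rm(list = cid, envir = st$members)
        st$typ[m] <- 0L
        st$cmplx[m] <- 0L
      })
  }
  unique(affected)
}

nf_merge_complexes <- function(st, a, b) {
  ca <- st$cmplx[a]; cb <- st$cmplx[b]
  if (ca == cb) return(invisible())
  ma <- st$members[[as.character(ca)]]
  mb <- st$members[[as.character(cb)]]
  if (length(ma) < length(mb)) { tmp <- ca; ca <- cb; cb <- tmp
                                 tmp <- ma; ma <- mb; mb <- tmp }
  st$cmplx[mb] <- ca
  st$members[[as.character(ca)]] <- c(ma, mb)
  rm(list = as.character(cb), envir = st$members)
  invisible()
}

nf_maybe_split <- function(st, a, b) {
  if (st$cmplx[a] != st$cmplx[b]) return(invisible())
  # BFS from a within the complex; if b not reached, split
  cid <- st$cmplx[a]
  mem <- st$members[[as.character(cid)]]
  seen <- a
  queue <- a
  while (length(queue)) {
    cur <- queue[1]; queue <- queue[-1]
    nb <- st$bmol[cur, ]
    nb <- nb[nb > 0L]
    new <- setdiff(nb, seen)
    seen <- c(seen, new)
    queue <- c(queue, new)
  }
  if (b %in% seen) return(invisible())
  rest <- setdiff(mem, seen)
  st$members[[as.character(cid)]] <- seen
  st$next_cmplx <- st$next_cmplx + 1L
  st$cmplx[rest] <- st$next_cmplx
  st$members[[as.character(st$next_cmplx)]] <- rest
  invisible()
}

# remove embeddings touching `affected`, re-match within them
nf_update_index <- function(st, affected) {
  for (j in seq_along(st$entries)) {
    E <- st$E[[j]]
    n <- ncol(E$mol)
    if (n) {
      hit <- colSums(matrix(E$mol %in% affected, nrow = nrow(E$mol))) > 0L
      if (any(hit)) {
        st$E[[j]] <- list(mol = E$mol[, !hit, drop = FALSE],
                          slot = E$slot[!hit])
        st$work <- st$work + sum(hit)
      }
    }
    live <- affected[st$typ[affected] > 0L]
    if (length(live)) {
      embs <- match_pattern(st$entries[[j]]$cp, st, restrict = live)
      if (length(embs)) {
        pk <- pack_embs(st$entries[[j]]$cp, embs)
        st$E[[j]] <- list(mol = cbind(st$E[[j]]$mol, pk$mol),
                          slot = c(st$E[[j]]$slot, pk$slot))
        st$work <- st$work + length(embs)
      }
    }
  }
  invisible(st)
}

# --- single event ------------------------------------------------------------

# One attempted event. If the drawn waiting time would pass `t_stop`, the
# clock is clamped there and nothing is applied (exact, by memorylessness
# of the exponential). Returns list(dt, rule, null, stopped).
nf_step <- function(st, scale = 1, t_stop = Inf) {
  rates <- nf_rates(st, scale)
  total <- sum(rates)
  if (total <= 0) {
    if (is.finite(t_stop)) st$time <- t_stop
    return(list(dt = Inf, rule = NA_integer_, null = TRUE, stopped = TRUE))
  }
  dt <- rexp(1, total)
  if (st$time + dt > t_stop) {
    st$time <- t_stop
    return(list(dt = dt, rule = NA_integer_, null = TRUE, stopped = TRUE))
  }
  r <- sample.int(length(rates), 1L, prob = rates)
  ru <- st$rules[[r]]
  chosen <- NULL
  if (ru$nslots == 1L) {
    j1 <- st$entry_of_rule[r, 1]
    n1 <- entry_count(st, j1)
    i1 <- sample.int(n1, 1L)
    chosen <- list(get_emb(st, j1, i1))
  } else if (ru$nslots == 2L) {
    j1 <- st$entry_of_rule[r, 1]; j2 <- st$entry_of_rule[r, 2]
    if (identical_entries(st, j1, j2)) {
      n1 <- entry_count(st, j1)
      i1 <- sample.int(n1, 1L)
      i2 <- sample.int(n1 - 1L, 1L)
      if (i2 >= i1) i2 <- i2 + 1L
      chosen <- list(get_emb(st, j1, i1), get_emb(st, j1, i2))
    } else {
      i1 <- sample.int(entry_count(st, j1), 1L)
      i2 <- sample.int(entry_count(st, j2), 1L)
      chosen <- list(get_emb(st, j1, i1), get_emb(st, j2, i2))
    }
    # molecularity: the two embeddings must lie in distinct complexes
    if (st$cmplx[chosen[[1]]$mol[1]] == st$cmplx[chosen[[2]]$mol[1]]) {
      st$time <- st$time + dt
      st$null_count <- st$null_count + 1L
      return(list(dt = dt, rule = r, null = TRUE, stopped = FALSE))
    }
  }
  affected <- nf_apply(st, r, chosen)
  nf_update_index(st, affected)
  st$time <- st$time + dt
  st$event_count <- st$event_count + 1L
  list(dt = dt, rule = r, null = FALSE, stopped = FALSE)
}

# full-recomputation audit of the incremental embedding index (debug mode)
nf_check_index <- function(st) {
  for (j in seq_along(st$entries)) {
    fresh <- pack_embs(st$entries[[j]]$cp,
                       match_pattern(st$entries[[j]]$cp, st))
    key <- function(E) sort(vapply(seq_len(ncol(E$mol)), function(i)
      paste(E$mol[, i], unlist(E$slot[[i]]), collapse = ","), character(1)))
    if (!identical(key(fresh), key(st$E[[j]]))) return(FALSE)
  }
  TRUE
}

get_emb <- function(st, j, i) {
  list(mol = st$E[[j]]$mol[, i], slot = st$E[[j]]$slot[[i]])
}

# --- observable evaluation ---------------------------------------------------

nf_observe <- function(st) {
  vapply(seq_along(st$obs), function(o) {
    js <- st$entry_of_obs[[o]]
    if (st$obs[[o]]$kind == "Molecules") {
      sum(vapply(js, function(j) entry_count(st, j), integer(1)))
    } else {
      cids <- unlist(lapply(js, function(j) {
        E <- st$E[[j]]
        if (!ncol(E$mol)) integer(0) else st$cmplx[E$mol[1, ]]
      }))
      length(unique(cids))
    }
  }, numeric(1))
}

# --- protocols ---------------------------------------------------------------

#' Define a simulation protocol
#'
#' A protocol holds an equilibration phase (simulated before time zero, with
#' no sampling) followed by species additions applied at time zero, e.g.
#' ligand doses. Additions are given as copies or as a molar concentration
#' plus the 3-D compartment to convert in.
#'
#' @param equilibrate seconds of pre-run simulation (steady-state burn-in;
#'   no automatic convergence detection is attempted).
#' @param additions list of `list(species =, copies =)` or
#'   `list(species =, conc =, compartment =)` entries.
#' @return object of class `sim_protocol`.
#' @export
sim_protocol <- function(equilibrate = 0, additions = list()) {
  structure(list(equilibrate = equilibrate, additions = additions),
            class = "sim_protocol")
}

resolve_addition_copies <- function(ad, model, scale) {
  if (!is.null(ad$copies)) return(round(ad$copies * scale))
  if (is.null(ad$conc)) stop("addition needs 'copies' or 'conc'")
  cmp <- model$compartments[[ad$compartment]]
  if (is.null(cmp)) stop("addition: unknown compartment ", ad$compartment)
  cmp$size <- cmp$size * scale
  convert_concentration(ad$conc, cmp)
}

seed_copy_number <- function(s, model) {
  copies <- s$copies
  if (is.character(copies)) copies <- model$parameters[[copies]]$value
  copies
}

# --- full run ----------------------------------------------------------------

#' Run a network-free stochastic simulation
#'
#' @param model a valid [rb_model()].
#' @param params named numeric vector/list overriding parameter values.
#' @param protocol a [sim_protocol()] (default: no equilibration, no
#'   additions).
#' @param t_end end time in seconds.
#' @param sample_dt observation grid spacing in seconds.
#' @param seed integer RNG seed (required: runs are reproducible per seed).
#' @param scale dimensionless compartment scale factor: seed and added copy
#'   numbers are multiplied by `scale` (rounded half to even) and
#'   bimolecular rate constants divided by it.
#' @param max_particles particle cap; exceeding it is an error suggesting a
#'   smaller `scale`.
#' @param record_work if `TRUE`, log per-event cost curves (cumulative
#'   embedding updates and cumulative CPU seconds) for cost-scaling
#'   analysis.
#' @return an `rb_trajectory`: `times`, `values` (time x observable count
#'   matrix), `observable_names`, `metadata`.
#' @export
simulate_network_free <- function(model, params = NULL, protocol = NULL,
                                  t_end, sample_dt, seed, scale = 1,
                                  max_particles = 1e6, record_work = FALSE) {
  stopifnot(t_end > 0, sample_dt > 0)
  set.seed(seed)
  crm <- compile_run_model(model, params)
  st <- nf_new_state(model, crm)
  total_seed <- 0
  for (s in model$seed_species) {
    cs <- compile_species(s$species, crm$reg)
    copies <- round(seed_copy_number(s, model) * scale)
    total_seed <- total_seed + copies * cs$k
    if (total_seed > max_particles) {
      stop("seed particle count exceeds max_particles (", max_particles,
           "); reduce the compartment scale factor")
    }
    nf_add_species(st, cs, copies)
  }
  nf_index_all(st)
  work_events <- numeric(0)
  work_vals <- numeric(0)
  work_cpu <- numeric(0)

  run_until <- function(t_stop) {
    repeat {
      ev <- nf_step(st, scale, t_stop = t_stop)
      if (ev$stopped) break
      if (record_work && !ev$null) {
        work_events <<- c(work_events, st$event_count)
        work_vals <<- c(work_vals, st$work)
        pt <- proc.time()
        work_cpu <<- c(work_cpu, pt[["user.self"]] + pt[["sys.self"]])
      }
    }
  }

  if (!is.null(protocol) && protocol$equilibrate > 0) {
    st$time <- -protocol$equilibrate
    run_until(0)
  }
  st$time <- 0
  if (!is.null(protocol)) {
    for (ad in protocol$additions) {
      sg <- if (is.character(ad$species)) parse_pattern(ad$species) else ad$species
      cs <- compile_species(sg, crm$reg)
      copies <- resolve_addition_copies(ad, model, scale)
      ids <- nf_add_species(st, cs, copies)
      nf_update_index(st, ids)
    }
  }

  times <- seq(0, t_end, by = sample_dt)
  values <- matrix(0, length(times), length(crm$obs))
  for (ti in seq_along(times)) {
    if (ti > 1L) run_until(times[ti])
    values[ti, ] <- nf_observe(st)
  }
  obs_names <- vapply(crm$obs, `[[`, character(1), "name")
  colnames(values) <- obs_names
  structure(list(times = times, values = values,
                 observable_names = obs_names,
                 metadata = list(method = "network_free", seed = seed,
                                 scale = scale,
                                 events = st$event_count,
                                 null_events = st$null_count,
                                 work = st$work,
                                 work_log = if (record_work)
                                   list(events = work_events,
                                        work = work_vals,
                                        cpu = work_cpu - work_cpu[1])
                                 else NULL)),
            class = "rb_trajectory")
}

#' @export
print.rb_trajectory <- function(x, ...) {
  cat("<rb_trajectory> method=", x$metadata$method,
      " seed=", x$metadata$seed,
      " times=[", min(x$times), ",", max(x$times), "] x ",
      length(x$observable_names), " observables\n", sep = "")
  invisible(x)
}

#' Export a trajectory as CSV plus JSON metadata sidecar
#'
#' @param traj an `rb_trajectory`.
#' @param path CSV output path; metadata is written to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  df <- data.frame(time = traj$times, traj$values, check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- traj$metadata
  meta$work_log <- NULL
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
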