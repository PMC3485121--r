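# Parameter ensembles: log-uniform sampling within feasibility classes,
# thermodynamic (detailed-balance) constraint enforcement on reversible
# binding cycles, and concentration/copy-number conversion.

#' Feasible ranges for the six parameter classes
#'
#' @return data frame with columns `class`, `low`, `high`, `units`.
#' @export
parameter_classes <- function() {
  data.frame(
    class = c("bimolecular_association", "unimolecular_dissociation",
              "phosphatase_catalyzed", "receptor_trafficking",
              "endocytic_degradation", "copy_number"),
    low  = c(1e-7, 1e-2, 1e-3, 1e-3, 1e-3, 1e4),
    high = c(1e-5, 1e0, 1e-1, 1e-1, 1e-1, 1e6),
    units = c("(molecules/cell)^-1 s^-1", "s^-1", "s^-1", "s^-1", "s^-1",
              "molecules/cell"),
    stringsAsFactors = FALSE)
}

class_range <- function(cls, classes = parameter_classes(),
                        diffusion_cap = NULL) {
  i <- match(cls, classes$class)
  if (is.na(i)) stop("unknown parameter class: ", cls)
  lo <- classes$low[i]; hi <- classes$high[i]
  if (cls == "bimolecular_association" && !is.null(diffusion_cap)) {
    hi <- min(hi, diffusion_cap)
  }
  c(lo, hi)
}

#' Sample a parameter ensemble
#'
#' Each class-assigned parameter is drawn log-uniformly within its class
#' range (ranges span about two orders of magnitude, so the scale-free
#' choice is uniform in log space); copy-number draws are rounded to
#' integers. Bimolecular association constants never exceed the diffusion
#' cap. Parameters marked `"fixed"` keep their model values. With
#' `detailed_balance = TRUE` every set is passed through
#' [enforce_detailed_balance()].
#'
#' @param model an [rb_model()].
#' @param class_map named character vector: parameter name to class name or
#'   `"fixed"`. Defaults to the `class` fields of the model's parameters
#'   (NA = fixed).
#' @param n number of parameter sets.
#' @param seed RNG seed (ensembles are reproducible per seed).
#' @param diffusion_cap upper bound on bimolecular association constants,
#'   (molecules/cell)^-1 s^-1. Defaults to the class upper bound.
#' @param detailed_balance enforce binding-cycle closure per set.
#' @return object of class `parameter_ensemble`: `sets` (list of named
#'   numeric vectors), `seed`, `class_map`, `ranges`, `adjustments`.
#' @export
sample_parameters <- function(model, class_map = NULL, n = 1000, seed = 1,
                              diffusion_cap = NULL, detailed_balance = TRUE) {
  if (is.null(class_map)) {
    class_map <- vapply(model$parameters, function(p)
      if (is.na(p$class)) "fixed" else p$class, character(1))
  }
  missing <- setdiff(names(model$parameters), names(class_map))
  if (length(missing)) {
    stop("parameters without a class assignment: ",
         paste(missing, collapse = ", "))
  }
  classes <- parameter_classes()
  set.seed(seed)
  dbg <- if (detailed_balance) db_structure(model) else NULL
  sets <- vector("list", n)
  adjustments <- vector("list", n)
  draw_set <- function() {
    vapply(names(model$parameters), function(nm) {
      cls <- class_map[[nm]]
      if (identical(cls, "fixed")) return(model$parameters[[nm]]$value)
      rg <- class_range(cls, classes, diffusion_cap)
      v <- exp(runif(1, log(rg[1]), log(rg[2])))
      if (cls == "copy_number") v <- round(v)
      v
    }, numeric(1))
  }
  for (i in seq_len(n)) {
    # rejection sampling: a draw whose cycle-closing constants cannot be
    # kept inside their class ranges is discarded and redrawn whole, so the
    # ensemble is log-uniform restricted to the thermodynamically feasible
    # region
    for (attempt in seq_len(1000L)) {
      vals <- draw_set()
      if (!detailed_balance || is.null(dbg) || !length(dbg$dependent)) {
        sets[[i]] <- vals
        break
      }
      res <- tryCatch(
        db_enforce_set(vals, dbg, class_map, classes, diffusion_cap),
        error = function(e) NULL)
      if (!is.null(res)) {
        sets[[i]] <- res$values
        adjustments[[i]] <- res$adjusted
        break
      }
      if (attempt == 1000L) {
        stop("could not sample a detailed-balance-feasible parameter set")
      }
    }
  }
  structure(list(sets = sets, seed = seed, class_map = class_map,
                 ranges = classes, adjustments = adjustments),
            class = "parameter_ensemble")
}

#' @export
print.parameter_ensemble <- function(x, ...) {
  cat("<parameter_ensemble> ", length(x$sets), " sets x ",
      length(x$sets[[1]]), " parameters (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

# --- detailed balance --------------------------------------------------------

# Identify reversible binding pairs and the stoichiometric cycle structure.
# A "binding pair" is a reversible rule pair whose forward diff consists of
# AddBond transformations only (catalytic, transport and degradation rules
# are irreversible energy-consuming steps, exempt from the constraint).
# Cycles are found on a bounded eager expansion of the reaction network from
# the model's seed species: one representative reaction per pair defines its
# stoichiometric column, and the left null space structure of that matrix
# (via QR) yields a spanning set of independent ("tree") pairs plus
# dependent cycle-closing pairs.
db_structure <- function(model, max_species = 500L) {
  pairs <- list()
  seen <- character(0)
  for (r in model$rules) {
    if (is.na(r$reversible_partner)) next
    if (r$name %in% seen) next
    partner <- model$rules[[r$reversible_partner]]
    if (is.null(partner)) next
    seen <- c(seen, r$name, partner$name)
    kinds_f <- vapply(derive_transformations(r), `[[`, character(1), "kind")
    kinds_b <- vapply(derive_transformations(partner), `[[`, character(1), "kind")
    if (all(kinds_f == "AddBond")) {
      pairs[[length(pairs) + 1L]] <- list(fwd = r$name, rev = partner$name,
                                          kf = r$rate_param,
                                          kr = partner$rate_param)
    } else if (all(kinds_b == "AddBond")) {
      pairs[[length(pairs) + 1L]] <- list(fwd = partner$name, rev = r$name,
                                          kf = partner$rate_param,
                                          kr = r$rate_param)
    }
  }
  if (!length(pairs)) return(NULL)
  crm <- compile_run_model(model)
  net <- otf_new_network(model, crm, max_species)
  for (s in model$seed_species) {
    cs <- compile_species(s$species, crm$reg)
    si <- otf_add_species(net, cs)
    net$pop[si] <- net$pop[si] + 1
  }
  repeat {
    todo <- which(!net$expanded[seq_along(net$species)])
    if (!length(todo) || net$capped) break
    for (si in todo) otf_expand_species(net, crm, si)
  }
  rule_names <- vapply(seq_along(net$rule_id), function(j)
    crm$rules[[net$rule_id[j]]]$name, character(1))
  S <- matrix(0, length(net$species), length(pairs))
  ok <- logical(length(pairs))
  for (q in seq_along(pairs)) {
    j <- which(rule_names == pairs[[q]]$fwd)[1]
    if (is.na(j)) next
    ok[q] <- TRUE
    S[net$r1[j], q] <- S[net$r1[j], q] - 1
    if (net$r2[j] > 0L) S[net$r2[j], q] <- S[net$r2[j], q] - 1
    for (pi in net$prod[[j]]) S[pi, q] <- S[pi, q] + 1
  }
  pairs <- pairs[ok]
  S <- S[, ok, drop = FALSE]
  if (!length(pairs)) return(NULL)
  qr_ <- qr(S)
  rank <- qr_$rank
  tree <- sort(qr_$pivot[seq_len(rank)])
  dependent <- setdiff(seq_along(pairs), tree)
  cycles <- lapply(dependent, function(j) {
    x <- qr.solve(S[, tree, drop = FALSE], S[, j])
    list(j = j, tree_coef = x)
  })
  list(pairs = pairs, S = S, tree = tree, dependent = dependent,
       cycles = cycles, capped = net$capped)
}

db_enforce_set <- function(vals, dbg, class_map, classes, diffusion_cap,
                           max_retry = 20L) {
  adjusted <- character(0)
  for (cy in dbg$cycles) {
    pj <- dbg$pairs[[cy$j]]
    lnK_tree <- vapply(dbg$tree, function(q) {
      p <- dbg$pairs[[q]]
      log(vals[[p$kf]]) - log(vals[[p$kr]])
    }, numeric(1))
    target_lnK <- sum(cy$tree_coef * lnK_tree)
    kr_cls <- class_map[[pj$kr]]
    rg <- if (identical(kr_cls, "fixed")) NULL
          else class_range(kr_cls, classes, diffusion_cap)
    for (try in seq_len(max_retry + 1L)) {
      kr_new <- vals[[pj$kf]] * exp(-target_lnK)
      if (is.null(rg) || (kr_new >= rg[1] && kr_new <= rg[2])) break
      if (try > max_retry) {
        stop("detailed balance: adjusted '", pj$kr,
             "' cannot be kept within its class range")
      }
      kf_cls <- class_map[[pj$kf]]
      if (identical(kf_cls, "fixed")) {
        stop("detailed balance: '", pj$kr, "' escapes its class range and '",
             pj$kf, "' is fixed")
      }
      kfr <- class_range(kf_cls, classes, diffusion_cap)
      vals[[pj$kf]] <- exp(runif(1, log(kfr[1]), log(kfr[2])))
    }
    if (abs(log(vals[[pj$kr]]) - log(kr_new)) > 1e-12) {
      adjusted <- c(adjusted, pj$kr)
    }
    vals[[pj$kr]] <- kr_new
  }
  list(values = vals, adjusted = adjusted)
}

#' Enforce detailed balance on one parameter set
#'
#' Reversible binding pairs define edges of a thermodynamic network; around
#' every independent reaction cycle the product of equilibrium constants
#' K = kf/kr must equal one. Spanning ("tree") pairs keep their sampled
#' values; each cycle-closing pair has its dissociation constant reset to
#' close its cycle exactly. Catalytic, trafficking and degradation rules are
#' exempt (irreversible, energy-consuming steps).
#'
#' @param param_set named numeric vector of parameter values.
#' @param model an [rb_model()] with reversible partner links.
#' @param class_map as in [sample_parameters()] (used for range checks on
#'   adjusted constants; `NULL` skips the check).
#' @return list: `values` (adjusted set), `adjusted` (names of reset
#'   parameters).
#' @export
enforce_detailed_balance <- function(param_set, model, class_map = NULL) {
  dbg <- db_structure(model)
  if (is.null(dbg) || !length(dbg$dependent)) {
    return(list(values = param_set, adjusted = character(0)))
  }
  if (is.null(class_map)) {
    class_map <- setNames(rep("fixed", length(param_set)), names(param_set))
    res <- db_enforce_set(param_set, dbg, class_map, parameter_classes(), NULL)
    return(res)
  }
  db_enforce_set(param_set, dbg, class_map, parameter_classes(), NULL)
}

#' Audit the detailed-balance constraint of a parameter set
#'
#' Recomputes, from scratch, every fundamental-cycle product of equilibrium
#' constants of the model's reversible binding pairs.
#'
#' @param param_set named numeric vector.
#' @param model an [rb_model()].
#' @return numeric vector of cycle products (all within tolerance of 1 for
#'   a thermodynamically consistent set); zero-length if the binding network
#'   is acyclic.
#' @export
detailed_balance_audit <- function(param_set, model) {
  dbg <- db_structure(model)
  if (is.null(dbg) || !length(dbg$dependent)) return(numeric(0))
  vapply(dbg$cycles, function(cy) {
    pj <- dbg$pairs[[cy$j]]
    lnK_j <- log(param_set[[pj$kf]]) - log(param_set[[pj$kr]])
    lnK_tree <- vapply(dbg$tree, function(q) {
      p <- dbg$pairs[[q]]
      log(param_set[[p$kf]]) - log(param_set[[p$kr]])
    }, numeric(1))
    exp(lnK_j - sum(cy$tree_coef * lnK_tree))
  }, numeric(1))
}

#' Convert a molar concentration to a copy number
#'
#' @param value molar concentration (mol/L).
#' @param compartment a 3-D [compartment()]; the effective volume is
#'   `size * scale_factor`.
#' @return integer copy number, `round(value * N_A * volume)`.
#' @export
convert_concentration <- function(value, compartment) {
  if (compartment$dimension != 3L) {
    stop("concentration conversion requires a 3-D compartment; ",
         "membrane species are specified as copies")
  }
  avogadro <- 6.02214076e23
  round(value * avogadro * compartment$size * compartment$scale_factor)
}

#' Export a parameter ensemble as CSV plus JSON manifest
#'
#' @param ensemble a `parameter_ensemble`.
#' @param path CSV path (one row per set, one column per parameter);
#'   manifest written to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_ensemble <- function(ensemble, path) {
  df <- as.data.frame(do.call(rbind, ensemble$sets))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  manifest <- list(seed = ensemble$seed,
                   n_sets = length(ensemble$sets),
                   class_map = as.list(ensemble$class_map),
                   ranges = ensemble$ranges,
                   n_adjusted = sum(vapply(ensemble$adjustments, length,
                                           integer(1))))
  jsonlite::write_json(manifest, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
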