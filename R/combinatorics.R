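# Exact enumeration of local docking-site states and closed-form
# monomer/dimer state-space counts.
#
# A docking site on a receptor is described by what can occupy it: it is
# unphosphorylated or phosphorylated (when phosphorylatable), or bound to
# one of the distinct adapter complexes that can assemble on it. Adapter
# complexes are described recursively: a binder molecule has its own
# modification states and child sites, each child site either empty or
# occupied by one of its own allowed sub-complexes, possibly gated on a
# modification state of the binder (e.g. GRB2 binds SHC1 only when SHC1 is
# phosphorylated). The number of possible states of a whole monomer is the
# product over its sites; dimer counts follow by pairing.
#
# Counts use exact integer arithmetic within the exactly-representable
# double range (< 2^53) and abort beyond it rather than losing precision.

#' Describe a binder (adapter) molecule recursively
#'
#' @param molecule binder molecule name.
#' @param modification_states character vector of the binder's own
#'   modification states (singleton for an unmodifiable binder).
#' @param child_sites list of child binding sites, each
#'   `list(name =, binders = list(<binder_spec>...), gating = <state or NA>)`:
#'   the child site can be empty or occupied by any allowed sub-complex of
#'   any of its binders, and is only occupiable when the parent's
#'   modification state equals `gating` (NA = always occupiable).
#' @return object of class `binder_spec`.
#' @export
binder_spec <- function(molecule, modification_states = "u", child_sites = list()) {
  stopifnot(is.character(molecule), length(modification_states) >= 1L)
  structure(list(molecule = molecule,
                 modification_states = modification_states,
                 child_sites = child_sites),
            class = "binder_spec")
}

#' Describe one local docking site
#'
#' @param name site name.
#' @param phospho_dependent if `TRUE` the unbound site has two states
#'   (unphosphorylated, phosphorylated); otherwise one (free).
#' @param binders list of [binder_spec()]s that can occupy the site.
#' @return object of class `site_spec`.
#' @export
site_spec <- function(name, phospho_dependent = FALSE, binders = list()) {
  if (inherits(binders, "binder_spec")) binders <- list(binders)
  nm <- vapply(binders, `[[`, character(1), "molecule")
  if (anyDuplicated(nm)) stop("binder names must be unique within a site")
  structure(list(name = name, phospho_dependent = phospho_dependent,
                 binders = binders),
            class = "site_spec")
}

#' Describe a whole molecule for state-space counting
#'
#' @param molecule molecule name.
#' @param sites ordered list of [site_spec()]s (a dual-specificity site is
#'   given as a list of site_specs sharing one position; see
#'   [count_dual_site()]).
#' @return object of class `molecule_state_spec`.
#' @export
molecule_state_spec <- function(molecule, sites) {
  structure(list(molecule = molecule, sites = sites),
            class = "molecule_state_spec")
}

exact_mult <- function(a, b) {
  x <- a * b
  if (x >= 2^53) stop("count exceeds the exactly representable integer range")
  x
}

# enumerate the distinct complexes attachable through one binder
enumerate_binder_complexes <- function(b, depth = 0L) {
  if (depth > 50L) stop("cyclic binder specification")
  out <- character(0)
  for (ms in b$modification_states) {
    child_opts <- lapply(b$child_sites, function(cs) {
      opts <- "-"
      gate <- cs$gating %||% NA_character_
      if (is.na(gate) || identical(gate, ms)) {
        for (sub in cs$binders) {
          opts <- c(opts, paste0(cs$name, "=",
                                 enumerate_binder_complexes(sub, depth + 1L)))
        }
      }
      opts
    })
    combos <- if (length(child_opts)) {
      grid <- do.call(expand.grid, c(child_opts,
                                     list(stringsAsFactors = FALSE)))
      apply(grid, 1L, paste, collapse = ",")
    } else ""
    out <- c(out, paste0(b$molecule, "~", ms, "[", combos, "]"))
  }
  unique(out)
}

#' Enumerate the distinct local states of a docking site
#'
#' States are the unbound states (one, or two when phosphorylatable) plus
#' one state per distinct adapter complex that can occupy the site,
#' enumerated recursively over binder modification states and gated child
#' sites. The canonical eight-state SHC1 docking site (unphosphorylated,
#' phosphorylated, SHC1, phospho-SHC1, SHC1:GRB2, SHC1:GRB2:SOS1,
#' SHC1:GRB2:GAB1, SHC1:GRB2:SOS1:GAB1) enumerates to exactly eight.
#'
#' @param site a [site_spec()].
#' @return character vector of distinct state descriptors; its length is the
#'   site's state count.
#' @export
enumerate_site_states <- function(site) {
  unbound <- if (site$phospho_dependent) c("unphos", "phos") else "free"
  bound <- unlist(lapply(site$binders, enumerate_binder_complexes))
  if (!length(bound)) return(unbound)
  unique(c(unbound, paste0("bound:", bound)))
}

#' Count the states of a dual-specificity docking site
#'
#' A physical site that serves as a docking site for several alternative
#' adapters has the union of their state sets: the shared unbound states
#' plus every distinct bound complex of every specification.
#'
#' @param specs list of [site_spec()]s describing the same physical site;
#'   their unbound states must agree.
#' @return integer count.
#' @export
count_dual_site <- function(specs) {
  ub <- lapply(specs, function(s)
    if (s$phospho_dependent) c("unphos", "phos") else "free")
  if (length(unique(ub)) != 1L) {
    stop("dual-site specifications disagree on unbound states")
  }
  states <- unique(unlist(lapply(specs, enumerate_site_states)))
  length(states)
}

site_count <- function(site) {
  if (inherits(site, "site_spec")) length(enumerate_site_states(site))
  else count_dual_site(site)
}

#' Count the possible states of a monomer
#'
#' Product over sites of the per-site local state counts; exact integer
#' arithmetic.
#'
#' @param spec a [molecule_state_spec()].
#' @return exact count (numeric, exact below 2^53).
#' @export
count_monomer_states <- function(spec) {
  counts <- vapply(spec$sites, site_count, numeric(1))
  Reduce(exact_mult, counts, accumulate = FALSE, right = FALSE, init = 1)
}

#' Count the possible states of a dimer
#'
#' For a heterodimer the count is the product of the monomer counts. For a
#' homodimer the two protomers are indistinguishable, so states are
#' unordered pairs with repetition: n(n+1)/2.
#'
#' @param a,b [molecule_state_spec()]s of the two protomers.
#' @return exact count.
#' @export
count_dimer_states <- function(a, b) {
  na <- count_monomer_states(a)
  if (!identical(a$molecule, b$molecule)) {
    nb <- count_monomer_states(b)
    return(exact_mult(na, nb))
  }
  exact_mult(na, na + 1) / 2
}
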