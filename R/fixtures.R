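# Programmatic model fixtures: docking-site specifications for state-space
# counting, toy models with known closed-form or exactly enumerable
# behavior, a reduced ERBB receptor signaling model, and random models for
# property testing.
#
# The reduced ERBB model is an original artifact authored for this package,
# consistent with canonical ERBB interaction-map semantics (ligands
# EGF/HRG; receptors EGFR/ERBB3; adapters SHC1, GRB2, SOS1, GAB1; PI3K;
# phospho-gated docking; nested adapter complexes); it is NOT a
# transcription of any full-scale model file, and its rate constants are
# mid-range defaults from the tabulated feasibility classes, not fitted
# values. Its manifest records this provenance.

# --- docking-site specifications --------------------------------------------

grb2_binder <- function() {
  binder_spec("GRB2", "u", child_sites = list(
    list(name = "sos1", binders = list(binder_spec("SOS1")), gating = NA),
    list(name = "gab1", binders = list(binder_spec("GAB1")), gating = NA)))
}

shc1_binder <- function() {
  binder_spec("SHC1", c("u", "p"), child_sites = list(
    list(name = "grb2", binders = list(grb2_binder()), gating = "p")))
}

#' Canonical docking-site specifications
#'
#' The four local site types of the EGFR/ERBB3 counting exercise: a ligand
#' binding site (2 states), a SHC1 docking site (8 states: unphosphorylated,
#' phosphorylated, SHC1, phospho-SHC1, SHC1:GRB2, SHC1:GRB2:SOS1,
#' SHC1:GRB2:GAB1, SHC1:GRB2:SOS1:GAB1), a GRB2 docking site (6 states) and
#' a PI3K docking site (3 states).
#'
#' @param ligand ligand name for the ligand site.
#' @return a [site_spec()].
#' @export
ligand_site_spec <- function(ligand = "EGF") {
  site_spec("ect", phospho_dependent = FALSE,
            binders = list(binder_spec(ligand)))
}

#' @rdname ligand_site_spec
#' @param name site (residue) name.
#' @export
shc1_site_spec <- function(name = "Yshc") {
  site_spec(name, phospho_dependent = TRUE, binders = list(shc1_binder()))
}

#' @rdname ligand_site_spec
#' @export
grb2_site_spec <- function(name = "Ygrb") {
  site_spec(name, phospho_dependent = TRUE, binders = list(grb2_binder()))
}

#' @rdname ligand_site_spec
#' @export
pi3k_site_spec <- function(name = "Ypik") {
  site_spec(name, phospho_dependent = TRUE,
            binders = list(binder_spec("PI3K")))
}

#' State-space specification of an EGFR monomer
#'
#' One EGF ligand site, two SHC1 docking sites, three GRB2 docking sites and
#' one dual GRB2/SHC1 docking site (Y1114), in the order matching the
#' canonical per-site factor sequence 2, 8, 6, 8, 12, 6, 6. Residue naming
#' is illustrative; the factor sequence is the authoritative structure.
#'
#' @return a [molecule_state_spec()] whose [count_monomer_states()] is
#'   331776.
#' @export
egfr_state_spec <- function() {
  molecule_state_spec("EGFR", list(
    ligand_site_spec("EGF"),
    shc1_site_spec("Y1"),
    grb2_site_spec("Y2"),
    shc1_site_spec("Y3"),
    list(grb2_site_spec("Y1114"), shc1_site_spec("Y1114")),  # dual site
    grb2_site_spec("Y5"),
    grb2_site_spec("Y6")))
}

#' State-space specification of an ERBB3 monomer
#'
#' One HRG ligand site, six PI3K docking sites and one SHC1 docking site
#' (factor sequence 2, 3^6, 8).
#'
#' @return a [molecule_state_spec()] whose [count_monomer_states()] is
#'   11664.
#' @export
erbb3_state_spec <- function() {
  molecule_state_spec("ERBB3", c(
    list(ligand_site_spec("HRG")),
    lapply(1:6, function(i) pi3k_site_spec(paste0("S", i))),
    list(shc1_site_spec("Y7"))))
}

# --- toy models --------------------------------------------------------------

#' Build a toy model with known behavior
#'
#' * `binding`: `A + B <-> AB`; the implied network has exactly 3 species
#'   and the equilibrium complex count solves the mass-action quadratic.
#' * `isomerization`: two-state flip with symmetric rates; long-time
#'   occupancy 1/2.
#' * `dimerization`: `A + A <-> AA`, exercising the symmetry factor 2.
#' * `multisite_phospho`: a receptor with 3 independent phosphosites;
#'   the full network is the 2^3 = 8 phosphoforms.
#' * `chain`: linear assembly A-B-C (6 species).
#' * `cycle_binding`: a receptor with two sites whose context-dependent
#'   binding rules form one thermodynamic cycle (detailed-balance fixture).
#'
#' @param name one of the names above.
#' @param copies seed copy number per molecule type (default 100).
#' @return an [rb_model()] carrying a `manifest` attribute with exact
#'   entity counts.
#' @export
build_toy <- function(name = c("binding", "isomerization", "dimerization",
                               "multisite_phospho", "chain", "cycle_binding"),
                      copies = 100) {
  name <- match.arg(name)
  m <- switch(name,
    binding = rb_model(
      molecule_types = list(molecule_type("A", "b"), molecule_type("B", "a")),
      parameters = list(rb_parameter("kon", 5e-4, class = "bimolecular_association"),
                        rb_parameter("koff", 0.1, class = "unimolecular_dissociation")),
      seed_species = list(list(species = "A(b)", copies = copies),
                          list(species = "B(a)", copies = copies)),
      rules = list(
        rb_rule("bind", list("A(b)", "B(a)"), list("A(b!1).B(a!1)"), "kon", "bind_rev"),
        rb_rule("bind_rev", list("A(b!1).B(a!1)"), list("A(b)", "B(a)"), "koff", "bind")),
      observables = list(rb_observable("AB", "Molecules", "A(b!+)"),
                         rb_observable("A_free", "Molecules", "A(b)"))),
    isomerization = rb_model(
      molecule_types = list(molecule_type("A", "s~U~P")),
      parameters = list(rb_parameter("kf", 0.1), rb_parameter("kr", 0.1)),
      seed_species = list(list(species = "A(s~U)", copies = copies)),
      rules = list(
        rb_rule("flip", list("A(s~U)"), list("A(s~P)"), "kf", "flip_rev"),
        rb_rule("flip_rev", list("A(s~P)"), list("A(s~U)"), "kr", "flip")),
      observables = list(rb_observable("Ap", "Molecules", "A(s~P)"),
                         rb_observable("Au", "Molecules", "A(s~U)"))),
    dimerization = rb_model(
      molecule_types = list(molecule_type("A", "b")),
      parameters = list(rb_parameter("kon", 5e-4, class = "bimolecular_association"),
                        rb_parameter("koff", 0.1, class = "unimolecular_dissociation")),
      seed_species = list(list(species = "A(b)", copies = copies)),
      rules = list(
        rb_rule("dim", list("A(b)", "A(b)"), list("A(b!1).A(b!1)"), "kon", "dim_rev"),
        rb_rule("dim_rev", list("A(b!1).A(b!1)"), list("A(b)", "A(b)"), "koff", "dim")),
      observables = list(rb_observable("AA", "Species", "A(b!1).A(b!1)"),
                         rb_observable("A_free", "Molecules", "A(b)"))),
    multisite_phospho = {
      rules <- list()
      obs <- list()
      for (i in 1:3) {
        y <- paste0("y", i)
        rules <- c(rules, list(
          rb_rule(paste0("phos_", y),
                  list(paste0("R(", y, "~U)")), list(paste0("R(", y, "~P)")), "kp"),
          rb_rule(paste0("dephos_", y),
                  list(paste0("R(", y, "~P)")), list(paste0("R(", y, "~U)")), "kd")))
        obs <- c(obs, list(rb_observable(paste0("p", y), "Molecules",
                                         paste0("R(", y, "~P)"))))
      }
      rb_model(
        molecule_types = list(molecule_type("R", "y1~U~P", "y2~U~P", "y3~U~P")),
        parameters = list(rb_parameter("kp", 0.1), rb_parameter("kd", 0.1)),
        seed_species = list(list(species = "R(y1~U,y2~U,y3~U)", copies = copies)),
        rules = rules, observables = obs)
    },
    chain = rb_model(
      molecule_types = list(molecule_type("A", "b"),
                            molecule_type("B", "a", "c"),
                            molecule_type("C", "b")),
      parameters = list(rb_parameter("kon", 5e-4, class = "bimolecular_association"),
                        rb_parameter("koff", 0.1, class = "unimolecular_dissociation")),
      seed_species = list(list(species = "A(b)", copies = copies),
                          list(species = "B(a,c)", copies = copies),
                          list(species = "C(b)", copies = copies)),
      rules = list(
        rb_rule("ab", list("A(b)", "B(a)"), list("A(b!1).B(a!1)"), "kon", "ab_rev"),
        rb_rule("ab_rev", list("A(b!1).B(a!1)"), list("A(b)", "B(a)"), "koff", "ab"),
        rb_rule("bc", list("B(c)", "C(b)"), list("B(c!1).C(b!1)"), "kon", "bc_rev"),
        rb_rule("bc_rev", list("B(c!1).C(b!1)"), list("B(c)", "C(b)"), "koff", "bc")),
      observables = list(rb_observable("ABC", "Species",
                                       "A(b!1).B(a!1,c!2).C(b!2)"))),
    cycle_binding = rb_model(
      molecule_types = list(molecule_type("R", "a", "b"),
                            molecule_type("A", "r"),
                            molecule_type("B", "r")),
      parameters = list(
        rb_parameter("kaf1", 1e-6, class = "bimolecular_association"),
        rb_parameter("kar1", 0.1, class = "unimolecular_dissociation"),
        rb_parameter("kaf2", 1e-6, class = "bimolecular_association"),
        rb_parameter("kar2", 0.1, class = "unimolecular_dissociation"),
        rb_parameter("kbf1", 1e-6, class = "bimolecular_association"),
        rb_parameter("kbr1", 0.1, class = "unimolecular_dissociation"),
        rb_parameter("kbf2", 1e-6, class = "bimolecular_association"),
        rb_parameter("kbr2", 0.1, class = "unimolecular_dissociation")),
      seed_species = list(list(species = "R(a,b)", copies = copies),
                          list(species = "A(r)", copies = copies),
                          list(species = "B(r)", copies = copies)),
      rules = list(
        rb_rule("bindA_free", list("R(a,b)", "A(r)"), list("R(a!1,b).A(r!1)"), "kaf1", "bindA_free_rev"),
        rb_rule("bindA_free_rev", list("R(a!1,b).A(r!1)"), list("R(a,b)", "A(r)"), "kar1", "bindA_free"),
        rb_rule("bindA_ctx", list("R(a,b!+)", "A(r)"), list("R(a!1,b!+).A(r!1)"), "kaf2", "bindA_ctx_rev"),
        rb_rule("bindA_ctx_rev", list("R(a!1,b!+).A(r!1)"), list("R(a,b!+)", "A(r)"), "kar2", "bindA_ctx"),
        rb_rule("bindB_free", list("R(a,b)", "B(r)"), list("R(a,b!1).B(r!1)"), "kbf1", "bindB_free_rev"),
        rb_rule("bindB_free_rev", list("R(a,b!1).B(r!1)"), list("R(a,b)", "B(r)"), "kbr1", "bindB_free"),
        rb_rule("bindB_ctx", list("R(a!+,b)", "B(r)"), list("R(a!+,b!1).B(r!1)"), "kbf2", "bindB_ctx_rev"),
        rb_rule("bindB_ctx_rev", list("R(a!+,b!1).B(r!1)"), list("R(a!+,b)", "B(r)"), "kbr2", "bindB_ctx")),
      observables = list(rb_observable("RAB", "Species", "A(r!1).R(a!1,b!2).B(r!2)"))))
  attr(m, "manifest") <- list(
    name = name,
    counts = list(molecule_types = length(m$molecule_types),
                  rules = length(m$rules),
                  parameters = length(m$parameters),
                  observables = length(m$observables),
                  seed_species = length(m$seed_species)))
  m
}

# --- reduced ERBB model ------------------------------------------------------

#' Build the reduced ERBB receptor signaling model
#'
#' Tier 1 covers ligand binding (EGF to EGFR, HRG to ERBB3), dimerization of
#' ligand-bound receptors (EGFR:EGFR, EGFR:ERBB3), transphosphorylation of
#' the 13 receptor tyrosines in dimer context, and phospho-gated adapter
#' recruitment (SHC1 with its own phosphosite and GRB2 relay; GRB2 with
#' independent SOS1 and GAB1 arms; PI3K on the six ERBB3 sites). Tier 2 adds
#' per-site dephosphorylation, a Ras to RAF to MEK to ERK backbone and a
#' PI3K to Akt arm with one activating site each, and ERK-dependent negative
#' feedback on a SOS1 site that gates GRB2:SOS1 association.
#'
#' The EGFR/ERBB3 site layout projects (via [erbb_site_projection()]) onto
#' the canonical docking-site specifications, so state-space counting of the
#' fixture reproduces the canonical monomer counts exactly.
#'
#' @param tier 1 or 2.
#' @param copies protein copy number per seed species, before compartment
#'   scaling (default 1e4, the low end of the feasible copy-number class,
#'   chosen so desk-scale stochastic runs stay tractable).
#' @return a validated [rb_model()] with a `manifest` attribute (entity
#'   counts, rule groups keyed to contact-map arrows, provenance notes).
#' @export
build_erbb_mini <- function(tier = 1, copies = 1e4) {
  stopifnot(tier %in% c(1, 2))
  egfr_y <- paste0("y", 1:6)
  erbb3_s <- c(paste0("s", 1:6), "y7")
  shc1_sites <- c("y1", "y3", "y4", "y7")
  grb2_sites <- c("y2", "y4", "y5", "y6")

  types <- list(
    molecule_type("EGF", "r", compartment = "Ex"),
    molecule_type("HRG", "r", compartment = "Ex"),
    do.call(molecule_type, c(list("EGFR", "l", "d"),
                             as.list(paste0(egfr_y, "~U~P")),
                             list(compartment = "M"))),
    do.call(molecule_type, c(list("ERBB3", "l", "d"),
                             as.list(paste0(erbb3_s, "~U~P")),
                             list(compartment = "M"))),
    molecule_type("SHC1", "ptb", "y~U~P"),
    molecule_type("GRB2", "sh2", "sh3n", "sh3c"),
    molecule_type("SOS1", "g", "f~U~P"),
    molecule_type("GAB1", "g"),
    molecule_type("PI3K", "sh2"))
  if (tier == 2) {
    types <- c(types, list(
      molecule_type("RAS", "s~D~T", compartment = "M"),
      molecule_type("RAF", "a~U~P"),
      molecule_type("MEK", "a~U~P"),
      molecule_type("ERK", "a~U~P"),
      molecule_type("AKT", "a~U~P")))
  }

  params <- list(
    rb_parameter("kon_lig", 1e-6, class = "bimolecular_association"),
    rb_parameter("koff_lig", 0.1, class = "unimolecular_dissociation"),
    rb_parameter("kon_dim", 1e-6, class = "bimolecular_association"),
    rb_parameter("koff_dim", 0.1, class = "unimolecular_dissociation"),
    rb_parameter("kon_dock", 1e-6, class = "bimolecular_association"),
    rb_parameter("koff_dock", 0.1, class = "unimolecular_dissociation"),
    rb_parameter("kphos", 1, class = NA_character_),
    rb_parameter("kact", 1e-6, class = "bimolecular_association"),
    rb_parameter("kdephos", 0.01, class = "phosphatase_catalyzed"))

  rules <- list()
  groups <- list()
  addr <- function(group, ...) {
    rs <- list(...)
    rules <<- c(rules, rs)
    groups[[group]] <<- c(groups[[group]],
                          vapply(rs, `[[`, character(1), "name"))
  }
  rev_pair <- function(name, lhs, rhs, kf, kr) {
    list(rb_rule(name, lhs, rhs, kf, paste0(name, "_rev")),
         rb_rule(paste0(name, "_rev"), rhs, lhs, kr, name))
  }

  do.call(addr, c(list("EGF-EGFR"),
                  rev_pair("lig_egf", list("EGF(r)", "EGFR(l)"),
                           list("EGF(r!1).EGFR(l!1)"), "kon_lig", "koff_lig")))
  do.call(addr, c(list("HRG-ERBB3"),
                  rev_pair("lig_hrg", list("HRG(r)", "ERBB3(l)"),
                           list("HRG(r!1).ERBB3(l!1)"), "kon_lig", "koff_lig")))
  do.call(addr, c(list("EGFR-EGFR"),
                  rev_pair("dim_ee", list("EGFR(l!+,d)", "EGFR(l!+,d)"),
                           list("EGFR(l!+,d!1).EGFR(l!+,d!1)"), "kon_dim", "koff_dim")))
  do.call(addr, c(list("EGFR-ERBB3"),
                  rev_pair("dim_eh", list("EGFR(l!+,d)", "ERBB3(l!+,d)"),
                           list("EGFR(l!+,d!1).ERBB3(l!+,d!1)"), "kon_dim", "koff_dim")))
  for (y in egfr_y) {
    addr("EGFR-transphos",
         rb_rule(paste0("tp_egfr_", y, "@enzyme=EGFR"),
                 list(paste0("EGFR(d!+,", y, "~U)")),
                 list(paste0("EGFR(d!+,", y, "~P)")), "kphos"))
  }
  for (s in erbb3_s) {
    addr("ERBB3-transphos",
         rb_rule(paste0("tp_erbb3_", s, "@enzyme=EGFR"),
                 list(paste0("ERBB3(d!+,", s, "~U)")),
                 list(paste0("ERBB3(d!+,", s, "~P)")), "kphos"))
  }
  for (y in c("y1", "y3", "y4")) {
    do.call(addr, c(list("pY-SHC1"),
                    rev_pair(paste0("dock_shc1_", y),
                             list(paste0("EGFR(", y, "~P)"), "SHC1(ptb)"),
                             list(paste0("EGFR(", y, "~P!1).SHC1(ptb!1)")),
                             "kon_dock", "koff_dock")))
  }
  do.call(addr, c(list("pY-SHC1"),
                  rev_pair("dock_shc1_y7",
                           list("ERBB3(y7~P)", "SHC1(ptb)"),
                           list("ERBB3(y7~P!1).SHC1(ptb!1)"),
                           "kon_dock", "koff_dock")))
  for (y in grb2_sites) {
    do.call(addr, c(list("pY-GRB2"),
                    rev_pair(paste0("dock_grb2_", y),
                             list(paste0("EGFR(", y, "~P)"), "GRB2(sh2)"),
                             list(paste0("EGFR(", y, "~P!1).GRB2(sh2!1)")),
                             "kon_dock", "koff_dock")))
  }
  for (s in paste0("s", 1:6)) {
    do.call(addr, c(list("pY-PI3K"),
                    rev_pair(paste0("dock_pi3k_", s),
                             list(paste0("ERBB3(", s, "~P)"), "PI3K(sh2)"),
                             list(paste0("ERBB3(", s, "~P!1).PI3K(sh2!1)")),
                             "kon_dock", "koff_dock")))
  }
  addr("SHC1-phos",
       rb_rule("shc1_phos@enzyme=EGFR", list("SHC1(ptb!+,y~U)"),
               list("SHC1(ptb!+,y~P)"), "kphos"))
  do.call(addr, c(list("SHC1-GRB2"),
                  rev_pair("shc1_grb2", list("SHC1(y~P)", "GRB2(sh2)"),
                           list("SHC1(y~P!1).GRB2(sh2!1)"),
                           "kon_dock", "koff_dock")))
  sos1_free <- if (tier == 2) "SOS1(g,f~U)" else "SOS1(g)"
  sos1_bound <- if (tier == 2) "GRB2(sh3n!1).SOS1(g!1,f~U)" else "GRB2(sh3n!1).SOS1(g!1)"
  do.call(addr, c(list("GRB2-SOS1"),
                  rev_pair("grb2_sos1", list("GRB2(sh3n)", sos1_free),
                           list(sos1_bound), "kon_dock", "koff_dock")))
  do.call(addr, c(list("GRB2-GAB1"),
                  rev_pair("grb2_gab1", list("GRB2(sh3c)", "GAB1(g)"),
                           list("GRB2(sh3c!1).GAB1(g!1)"),
                           "kon_dock", "koff_dock")))

  obs <- list()
  for (y in egfr_y) {
    obs <- c(obs, list(rb_observable(paste0("pEGFR_", y), "Molecules",
                                     paste0("EGFR(", y, "~P!?)"))))
  }
  for (s in erbb3_s) {
    obs <- c(obs, list(rb_observable(paste0("pERBB3_", s), "Molecules",
                                     paste0("ERBB3(", s, "~P!?)"))))
  }
  obs <- c(obs, list(rb_observable("pSHC1_y", "Molecules", "SHC1(y~P!?)")))

  if (tier == 2) {
    for (y in egfr_y) {
      addr("dephos", rb_rule(paste0("dp_egfr_", y),
                             list(paste0("EGFR(", y, "~P)")),
                             list(paste0("EGFR(", y, "~U)")), "kdephos"))
    }
    for (s in erbb3_s) {
      addr("dephos", rb_rule(paste0("dp_erbb3_", s),
                             list(paste0("ERBB3(", s, "~P)")),
                             list(paste0("ERBB3(", s, "~U)")), "kdephos"))
    }
    addr("dephos", rb_rule("dp_shc1", list("SHC1(y~P)"), list("SHC1(y~U)"), "kdephos"))
    addr("SOS1-RAS",
         rb_rule("ras_act@enzyme=SOS1", list("SOS1(g!+)", "RAS(s~D)"),
                 list("SOS1(g!+)", "RAS(s~T)"), "kact"))
    addr("RAS-RAF",
         rb_rule("raf_act@enzyme=RAS", list("RAS(s~T)", "RAF(a~U)"),
                 list("RAS(s~T)", "RAF(a~P)"), "kact"))
    addr("RAF-MEK",
         rb_rule("mek_act@enzyme=RAF", list("RAF(a~P)", "MEK(a~U)"),
                 list("RAF(a~P)", "MEK(a~P)"), "kact"))
    addr("MEK-ERK",
         rb_rule("erk_act@enzyme=MEK", list("MEK(a~P)", "ERK(a~U)"),
                 list("MEK(a~P)", "ERK(a~P)"), "kact"))
    addr("PI3K-AKT",
         rb_rule("akt_act@enzyme=PI3K", list("PI3K(sh2!+)", "AKT(a~U)"),
                 list("PI3K(sh2!+)", "AKT(a~P)"), "kact"))
    addr("ERK-SOS1-feedback",
         rb_rule("fb_sos1@enzyme=ERK", list("ERK(a~P)", "SOS1(f~U)"),
                 list("ERK(a~P)", "SOS1(f~P)"), "kact"))
    addr("dephos",
         rb_rule("dp_ras", list("RAS(s~T)"), list("RAS(s~D)"), "kdephos"),
         rb_rule("dp_raf", list("RAF(a~P)"), list("RAF(a~U)"), "kdephos"),
         rb_rule("dp_mek", list("MEK(a~P)"), list("MEK(a~U)"), "kdephos"),
         rb_rule("dp_erk", list("ERK(a~P)"), list("ERK(a~U)"), "kdephos"),
         rb_rule("dp_akt", list("AKT(a~P)"), list("AKT(a~U)"), "kdephos"),
         rb_rule("dp_sos1", list("SOS1(f~P)"), list("SOS1(f~U)"), "kdephos"))
    obs <- c(obs, list(
      rb_observable("pRAS", "Molecules", "RAS(s~T)"),
      rb_observable("pRAF", "Molecules", "RAF(a~P)"),
      rb_observable("pMEK", "Molecules", "MEK(a~P)"),
      rb_observable("pERK", "Molecules", "ERK(a~P)"),
      rb_observable("pAKT", "Molecules", "AKT(a~P)"),
      rb_observable("pSOS1_f", "Molecules", "SOS1(f~P)")))
  }

  seeds <- list(
    list(species = paste0("EGFR(l,d,", paste0(egfr_y, "~U", collapse = ","), ")"),
         copies = copies),
    list(species = paste0("ERBB3(l,d,", paste0(erbb3_s, "~U", collapse = ","), ")"),
         copies = copies),
    list(species = "SHC1(ptb,y~U)", copies = copies),
    list(species = "GRB2(sh2,sh3n,sh3c)", copies = copies),
    list(species = if (tier == 2) "SOS1(g,f~U)" else "SOS1(g,f~U)", copies = copies),
    list(species = "GAB1(g)", copies = copies),
    list(species = "PI3K(sh2)", copies = copies))
  if (tier == 2) {
    seeds <- c(seeds, list(
      list(species = "RAS(s~D)", copies = copies),
      list(species = "RAF(a~U)", copies = copies),
      list(species = "MEK(a~U)", copies = copies),
      list(species = "ERK(a~U)", copies = copies),
      list(species = "AKT(a~U)", copies = copies)))
  }

  compartments <- list(
    compartment("Ex", 3, 1e-10),
    compartment("M", 2, 1),
    compartment("C", 3, 2e-12),
    compartment("En", 3, 1e-14))

  m <- rb_model(molecule_types = types, compartments = compartments,
                parameters = params, seed_species = seeds,
                rules = rules, observables = obs)
  attr(m, "manifest") <- list(
    name = paste0("erbb_mini_tier", tier),
    provenance = paste(
      "Original reduced ERBB signaling model authored for this package;",
      "consistent with canonical ERBB interaction-map semantics but not",
      "a transcription of any full-scale model file."),
    counts = list(molecule_types = length(types),
                  rules = length(rules),
                  parameters = length(params),
                  observables = length(obs),
                  seed_species = length(seeds)),
    rule_groups = groups,
    binding_edges = list(
      c("EGF.r", "EGFR.l"), c("HRG.r", "ERBB3.l"),
      c("EGFR.d", "EGFR.d"), c("EGFR.d", "ERBB3.d"),
      c("EGFR.y1", "SHC1.ptb"), c("EGFR.y3", "SHC1.ptb"),
      c("EGFR.y4", "SHC1.ptb"), c("ERBB3.y7", "SHC1.ptb"),
      c("EGFR.y2", "GRB2.sh2"), c("EGFR.y4", "GRB2.sh2"),
      c("EGFR.y5", "GRB2.sh2"), c("EGFR.y6", "GRB2.sh2"),
      c("ERBB3.s1", "PI3K.sh2"), c("ERBB3.s2", "PI3K.sh2"),
      c("ERBB3.s3", "PI3K.sh2"), c("ERBB3.s4", "PI3K.sh2"),
      c("ERBB3.s5", "PI3K.sh2"), c("ERBB3.s6", "PI3K.sh2"),
      c("SHC1.y", "GRB2.sh2"), c("GRB2.sh3n", "SOS1.g"),
      c("GRB2.sh3c", "GAB1.g")))
  m
}

#' Project the reduced ERBB receptor types onto counting specifications
#'
#' Maps the EGFR or ERBB3 molecule type of [build_erbb_mini()] onto the
#' corresponding [molecule_state_spec()], so the fixture's site layout and
#' the combinatorial counts are checked against each other.
#'
#' @param receptor `"EGFR"` or `"ERBB3"`.
#' @return a [molecule_state_spec()].
#' @export
erbb_site_projection <- function(receptor = c("EGFR", "ERBB3")) {
  receptor <- match.arg(receptor)
  if (receptor == "EGFR") egfr_state_spec() else erbb3_state_spec()
}

# --- random models -----------------------------------------------------------

#' Generate a random valid model
#'
#' Small random models (binding/unbinding and state-flip rules over random
#' molecule types) for property tests: every generated model validates
#' cleanly and round-trips through the text dialect. Rules that cannot fire
#' on any species reachable from the seeds within a bounded eager network
#' expansion are flagged inert in the manifest.
#'
#' @param n_types number of molecule types (<= 8).
#' @param n_rules number of unidirectional rules to aim for (<= 20).
#' @param max_sites maximum components per type.
#' @param seed RNG seed.
#' @return an [rb_model()] with a `manifest` attribute.
#' @export
random_model <- function(n_types = 3, n_rules = 6, max_sites = 3, seed = 1) {
  stopifnot(n_types <= 8, n_rules <= 20)
  set.seed(seed)
  types <- lapply(seq_len(n_types), function(i) {
    nsite <- sample.int(max_sites, 1L)
    comps <- vapply(seq_len(nsite), function(s) {
      nm <- paste0("c", s)
      if (runif(1) < 0.4) paste0(nm, "~U~P") else nm
    }, character(1))
    do.call(molecule_type, c(list(paste0("T", i)), as.list(comps)))
  })
  tinfo <- lapply(types, function(t) list(
    name = t$name,
    comps = vapply(t$comps, `[[`, character(1), "name"),
    stateful = vapply(t$comps, function(cc) length(cc$states) > 0, logical(1))))
  params <- list(rb_parameter("kon", 1e-3, class = "bimolecular_association"),
                 rb_parameter("koff", 0.1, class = "unimolecular_dissociation"),
                 rb_parameter("kflip", 0.05))
  rules <- list()
  used <- character(0)
  tries <- 0L
  while (length(rules) < n_rules && tries < 200L) {
    tries <- tries + 1L
    if (runif(1) < 0.6) {
      # binding + its reverse
      ta <- tinfo[[sample.int(n_types, 1L)]]
      tb <- tinfo[[sample.int(n_types, 1L)]]
      ca <- ta$comps[sample.int(length(ta$comps), 1L)]
      cb <- tb$comps[sample.int(length(tb$comps), 1L)]
      key <- paste("bind", ta$name, ca, tb$name, cb)
      if (key %in% used) next
      if (ta$name == tb$name && ca == cb) next  # keep symmetry simple here
      used <- c(used, key)
      nm <- paste0("b", length(rules) + 1L)
      lhs <- list(paste0(ta$name, "(", ca, ")"), paste0(tb$name, "(", cb, ")"))
      rhs <- list(paste0(ta$name, "(", ca, "!1).", tb$name, "(", cb, "!1)"))
      rules <- c(rules, list(
        rb_rule(nm, lhs, rhs, "kon", paste0(nm, "_rev")),
        rb_rule(paste0(nm, "_rev"), rhs, lhs, "koff", nm)))
    } else {
      ta <- tinfo[[sample.int(n_types, 1L)]]
      sc <- which(ta$stateful)
      if (!length(sc)) next
      cc <- ta$comps[sc[sample.int(length(sc), 1L)]]
      dir <- sample(c("U", "P"), 2L)
      key <- paste("flip", ta$name, cc, dir[1])
      if (key %in% used) next
      used <- c(used, key)
      nm <- paste0("f", length(rules) + 1L)
      rules <- c(rules, list(
        rb_rule(nm, list(paste0(ta$name, "(", cc, "~", dir[1], ")")),
                list(paste0(ta$name, "(", cc, "~", dir[2], ")")), "kflip")))
    }
  }
  seeds <- lapply(tinfo, function(t) {
    comps <- vapply(seq_along(t$comps), function(s)
      if (t$stateful[s]) paste0(t$comps[s], "~U") else t$comps[s], character(1))
    list(species = paste0(t$name, "(", paste(comps, collapse = ","), ")"),
         copies = 20)
  })
  m <- rb_model(molecule_types = types, parameters = params,
                seed_species = seeds, rules = rules,
                observables = list(rb_observable(
                  "free_T1", "Molecules",
                  paste0("T1(", tinfo[[1]]$comps[1], ")"))))
  # inertness: eager bounded expansion, flag rules with no generated channel
  crm <- compile_run_model(m)
  net <- otf_new_network(m, crm, max_species = 60L, max_reactions = 300L)
  for (s in m$seed_species) {
    cs <- compile_species(s$species, crm$reg)
    si <- otf_add_species(net, cs)
    net$pop[si] <- net$pop[si] + s$copies
  }
  repeat {
    todo <- which(!net$expanded[seq_along(net$species)])
    if (!length(todo) || net$capped) break
    for (si in todo) otf_expand_species(net, crm, si)
  }
  fired <- unique(vapply(net$rule_id, function(r) crm$rules[[r]]$name, character(1)))
  inert <- setdiff(names(m$rules), fired)
  attr(m, "manifest") <- list(
    name = paste0("random_", seed),
    counts = list(molecule_types = length(types), rules = length(rules),
                  parameters = length(params), observables = 1L,
                  seed_species = length(seeds)),
    inert_rules = if (net$capped) NA else inert)
  m
}
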