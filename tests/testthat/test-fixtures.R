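# Fixture generators: manifests, reduced ERBB model structure, random models.

test_that("every toy fixture validates and its manifest matches exactly", {
  for (nm in c("binding", "isomerization", "dimerization",
               "multisite_phospho", "chain", "cycle_binding")) {
    m <- build_toy(nm)
    d <- validate_model(m)
    expect_identical(sum(d$severity == "error"), 0L, info = nm)
    man <- attr(m, "manifest")
    expect_identical(man$counts$molecule_types, length(m$molecule_types))
    expect_identical(man$counts$rules, length(m$rules))
    expect_identical(man$counts$parameters, length(m$parameters))
    expect_identical(man$counts$observables, length(m$observables))
    expect_identical(man$counts$seed_species, length(m$seed_species))
  }
})

test_that("the reduced ERBB receptors project onto the canonical state counts", {
  m <- build_erbb_mini(1)
  expect_identical(sum(validate_model(m)$severity == "error"), 0L)
  expect_identical(count_monomer_states(erbb_site_projection("EGFR")), 331776)
  expect_identical(count_monomer_states(erbb_site_projection("ERBB3")), 11664)
  expect_gte(count_dimer_states(erbb_site_projection("EGFR"),
                                erbb_site_projection("ERBB3")), 3.8e9)
  expect_gte(count_dimer_states(erbb_site_projection("EGFR"),
                                erbb_site_projection("EGFR")), 5.5e10)
  # the EGFR type carries the ligand site, dimer site and six tyrosines
  egfr <- m$molecule_types[["EGFR"]]
  expect_identical(length(egfr$comps), 8L)
  expect_identical(sum(vapply(egfr$comps, function(cc)
    identical(cc$states, c("U", "P")), logical(1))), 6L)
  # 13 transphosphorylation rules: 6 EGFR + 7 ERBB3 receptor tyrosines
  expect_identical(sum(grepl("^tp_", names(m$rules))), 13L)
  # one phosphosite observable per receptor tyrosine plus the SHC1 site
  expect_identical(length(m$observables), 14L)
})

test_that("tier 2 dosing produces more varying phosphosite shapes than constant ones", {
  m <- build_erbb_mini(2)
  expect_identical(sum(validate_model(m)$severity == "error"), 0L)
  pro <- sim_protocol(additions = list(
    list(species = "EGF(r)", conc = 5e-9, compartment = "Ex"),
    list(species = "HRG(r)", conc = 5e-9, compartment = "Ex")))
  tr <- simulate_network_free(m, protocol = pro, t_end = 40, sample_dt = 10,
                              seed = 17, scale = 0.005)
  tc <- timecourse_matrix(tr)
  varying <- sum(apply(tc, 1, function(x) stats::sd(x) > 0))
  constant <- nrow(tc) - varying
  expect_gt(varying, constant)
})

test_that("random models are deterministic per seed and flag inert rules", {
  m1 <- random_model(4, 8, 3, seed = 7)
  m2 <- random_model(4, 8, 3, seed = 7)
  expect_identical(write_model(m1), write_model(m2))
  man <- attr(m1, "manifest")
  expect_true(!is.null(man$inert_rules))
  # flagged rules are exactly those without a generated reaction channel
  expect_true(all(man$inert_rules %in% names(m1$rules)) || anyNA(man$inert_rules))
  expect_identical(sum(validate_model(m1)$severity == "error"), 0L)
})

test_that("fixture files regenerate deterministically through the CLI surface", {
  out1 <- file.path(tempdir(), "fx1"); out2 <- file.path(tempdir(), "fx2")
  expect_identical(rbnet_cli(c("fixtures", "--name", "binding", "--out", out1)), 0L)
  expect_identical(rbnet_cli(c("fixtures", "--name", "binding", "--out", out2)), 0L)
  expect_identical(readLines(file.path(out1, "binding.bngl")),
                   readLines(file.path(out2, "binding.bngl")))
  m <- parse_model(paste(readLines(file.path(out1, "binding.bngl")),
                         collapse = "\n"))
  expect_identical(length(m$rules), 2L)
  man <- jsonlite::read_json(file.path(out1, "binding_manifest.json"))
  expect_identical(man$counts$rules, 2L)
})
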