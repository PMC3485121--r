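# Text dialect: pattern parsing, model round trips, negative corpus.

test_that("pattern expressions parse to the expected structures", {
  g <- parse_pattern("A(b!1).B(a!1)")
  expect_length(g$mols, 2L)
  expect_identical(g$mols[[1]]$comps[[1]]$bond, "1")

  g2 <- parse_pattern("R(y~P!+)")
  expect_identical(g2$mols[[1]]$comps[[1]]$state, "P")
  expect_identical(g2$mols[[1]]$comps[[1]]$bond, "+")

  g3 <- parse_pattern("R(y)")
  expect_identical(g3$mols[[1]]$comps[[1]]$bond, "0")   # unbound by convention
  expect_true(is.na(g3$mols[[1]]$comps[[1]]$state))     # state wildcard

  g4 <- parse_pattern("R(y~P!?)@En")
  expect_identical(g4$mols[[1]]$comps[[1]]$bond, "?")
  expect_identical(g4$mols[[1]]$compartment, "En")
})

test_that("a minimal model and a reversible rule parse as specified", {
  txt <- "
begin molecule types
  A(b)
end molecule types
begin seed species
  A(b) 100
end seed species
"
  m <- parse_model(txt)
  expect_length(m$molecule_types, 1L)
  expect_length(m$seed_species, 1L)
  expect_identical(m$seed_species[[1]]$copies, 100)

  txt2 <- "
begin parameters
  kf 1e-3
  kr 0.1
end parameters
begin molecule types
  A(b)
  B(a)
end molecule types
begin reaction rules
  A(b) + B(a) <-> A(b!1).B(a!1) kf, kr
end reaction rules
"
  m2 <- parse_model(txt2)
  expect_length(m2$rules, 2L)
  expect_identical(m2$rules[[1]]$reversible_partner, names(m2$rules)[2])
  expect_identical(m2$rules[[2]]$reversible_partner, names(m2$rules)[1])
})

test_that("write_model round-trips all fixtures deterministically", {
  fixtures <- c("binding", "isomerization", "dimerization",
                "multisite_phospho", "chain", "cycle_binding")
  for (fx in fixtures) {
    m <- build_toy(fx)
    txt <- write_model(m)
    expect_identical(write_model(m), txt)                 # byte-determinism
    m2 <- parse_model(txt)
    expect_identical(write_model(m2), txt, info = fx)     # structural round trip
    expect_identical(names(m2$rules), names(m$rules))
    expect_identical(length(m2$observables), length(m$observables))
  }
  for (tier in 1:2) {
    m <- build_erbb_mini(tier)
    txt <- write_model(m)
    expect_identical(write_model(parse_model(txt)), txt)
    man <- attr(m, "manifest")
    expect_identical(length(m$rules), man$counts$rules)
    expect_identical(length(m$molecule_types), man$counts$molecule_types)
    expect_identical(length(m$observables), man$counts$observables)
  }
})

test_that("wildcard observables survive the round trip verbatim", {
  m <- build_erbb_mini(1)
  txt <- write_model(m)
  expect_match(txt, "EGFR(y1~P!?)", fixed = TRUE)
  m2 <- parse_model(txt)
  expect_identical(m2$observables[["pEGFR_y1"]]$patterns[[1]]$mols[[1]]$comps[[1]]$bond,
                   "?")
})

test_that("random models round-trip through the dialect", {
  sizes <- list(c(2, 4), c(3, 6), c(4, 8), c(5, 10), c(3, 9),
                c(2, 6), c(4, 10), c(5, 6), c(3, 4), c(4, 6))
  for (seed in seq_along(sizes)) {
    m <- random_model(n_types = sizes[[seed]][1], n_rules = sizes[[seed]][2],
                      seed = seed)
    txt <- write_model(m)
    expect_identical(write_model(parse_model(txt)), txt, info = seed)
  }
})

test_that("the parser rejects malformed inputs with positioned errors", {
  negatives <- c(
    "begin molecule types\nA(b\nend molecule types",          # unclosed paren
    "begin molecule types\nA(b)\nend molecule types\nbegin molecule types\nB(a)\nend molecule types", # duplicate block
    "begin reaction rules\nA(b) -> A(b!1) k\nend reaction rules", # dangling !1
    "begin molecule types\nA(b)",                              # unclosed block
    "A(b) 100",                                                # content outside block
    "begin reaction rules\nA(b) B(a) k\nend reaction rules")   # no arrow
  for (txt in negatives) {
    expect_error(parse_model(txt), info = txt)
  }
  expect_error(parse_pattern("A(b!1)"), "bond label")
  expect_error(parse_model("begin parameters\nk one\nend parameters"), "numeric")
})
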