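# Model representation, validation diagnostics, and rule diffs.

toy_ab <- function() build_toy("binding")

test_that("well-formed models validate cleanly and invariant breaks are diagnosed", {
  expect_identical(nrow(validate_model(toy_ab())), 0L)

  # rule referencing an undeclared component
  bad <- rb_model(
    molecule_types = list(molecule_type("A", "b")),
    parameters = list(rb_parameter("k", 1)),
    rules = list(rb_rule("r", list("A(x)"), list("A(x)"), "k")))
  d <- validate_model(bad)
  expect_true(any(d$severity == "error" & grepl("x", d$message)))

  # undeclared rate parameter
  bad2 <- rb_model(
    molecule_types = list(molecule_type("A", "s~U~P")),
    rules = list(rb_rule("r", list("A(s~U)"), list("A(s~P)"), "missing_k")))
  d2 <- validate_model(bad2)
  expect_true(any(d2$severity == "error" & grepl("missing_k", d2$message)))

  # two bonds on one component endpoint are rejected at construction
  expect_error(parse_pattern("A(b!1!2)"))
  expect_error(parse_pattern("A(b!1).B(a!1).B(a!1)"), "two endpoints")

  # non-integer copy number
  bad4 <- rb_model(
    molecule_types = list(molecule_type("A", "b")),
    seed_species = list(list(species = "A(b)", copies = 2.5)))
  d4 <- validate_model(bad4)
  expect_true(any(d4$severity == "error" & grepl("copy number", d4$message)))
})

test_that("rule diffs recover bond, state, and molecule changes", {
  m <- toy_ab()
  tfs <- derive_transformations(m$rules[["bind"]])
  expect_identical(vapply(tfs, `[[`, character(1), "kind"), "AddBond")

  r <- rb_rule("phos", list("R(y~U)"), list("R(y~P)"), "k")
  mphos <- rb_model(molecule_types = list(molecule_type("R", "y~U~P")),
                    parameters = list(rb_parameter("k", 1)), rules = list(r))
  tfs2 <- derive_transformations(r)
  expect_identical(vapply(tfs2, `[[`, character(1), "kind"), "ChangeState")
  expect_identical(tfs2[[1]]$state, "P")

  # unbinding + degradation of the ligand
  r3 <- rb_rule("deg", list("L(r!1).R(l!1)"), list("R(l)"), "k")
  tfs3 <- derive_transformations(r3)
  expect_setequal(vapply(tfs3, `[[`, character(1), "kind"),
                  c("DeleteBond", "DeleteMolecule"))
})

test_that("applying a derived diff reproduces the product side (round trip)", {
  models <- list(build_toy("binding"), build_toy("dimerization"),
                 build_toy("chain"), build_toy("multisite_phospho"),
                 build_toy("cycle_binding"), build_erbb_mini(2))
  for (m in models) {
    for (r in m$rules) {
      tfs <- derive_transformations(r)
      out <- apply_transformations(r$reactants, tfs)
      expect_equal(length(out), length(r$products), info = r$name)
      # product multisets must match up to pattern isomorphism
      remaining <- seq_along(r$products)
      for (g in out) {
        hit <- 0L
        for (q in remaining) {
          reg <- rbnet:::compile_registry(m)
          same <- rbnet:::pattern_iso_count(
            rbnet:::compile_pattern(g, reg),
            rbnet:::compile_pattern(r$products[[q]], reg),
            count_all = FALSE) > 0L
          if (same) { hit <- q; break }
        }
        expect_true(hit > 0L, info = paste(r$name, "produced", format(g)))
        remaining <- setdiff(remaining, hit)
      }
    }
  }
})

test_that("identical-molecule correspondence ambiguity is an error, not a guess", {
  # two A's whose written product forms are indistinguishable but whose
  # pairing changes the diff (which one gets phosphorylated)
  r <- rb_rule("amb",
               list("B(b!1,c!2).A(x!1,y~U).A(x!2,y~P)"),
               list("B(b!1,c!2).A(x!1,y~P).A(x!2,y~P)"), "k")
  expect_error(derive_transformations(r), "ambiguous")

  # symmetric dimerization is NOT ambiguous (swap gives the same bond)
  r2 <- build_toy("dimerization")$rules[["dim"]]
  expect_silent(derive_transformations(r2))
})
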