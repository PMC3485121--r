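# Parameter ensembles: class ranges, log-uniformity, determinism,
# detailed-balance enforcement, unit conversion.

test_that("class draws respect ranges and copy numbers are integers", {
  m <- rb_model(
    molecule_types = list(molecule_type("A", "b"), molecule_type("B", "a")),
    parameters = list(
      rb_parameter("kon", 1e-6, class = "bimolecular_association"),
      rb_parameter("koff", 0.1, class = "unimolecular_dissociation"),
      rb_parameter("nA", 1e5, class = "copy_number"),
      rb_parameter("fixed_k", 2, class = NA_character_)))
  ens <- sample_parameters(m, n = 300, seed = 4, detailed_balance = FALSE)
  kon <- vapply(ens$sets, `[[`, numeric(1), "kon")
  koff <- vapply(ens$sets, `[[`, numeric(1), "koff")
  nA <- vapply(ens$sets, `[[`, numeric(1), "nA")
  expect_true(all(kon >= 1e-7 & kon <= 1e-5))
  expect_true(all(koff >= 1e-2 & koff <= 1))
  expect_true(all(nA >= 1e4 & nA <= 1e6))
  expect_true(all(nA == round(nA)))
  expect_true(all(vapply(ens$sets, `[[`, numeric(1), "fixed_k") == 2))
  # diffusion cap narrows the bimolecular range
  ens2 <- sample_parameters(m, n = 100, seed = 4, diffusion_cap = 2e-6,
                            detailed_balance = FALSE)
  expect_true(all(vapply(ens2$sets, `[[`, numeric(1), "kon") <= 2e-6))
  # unassigned parameters are an error listing names
  expect_error(sample_parameters(m, class_map = c(kon = "bimolecular_association"),
                                 n = 2, seed = 1),
               "koff")
})

test_that("draws are log-uniform (Kolmogorov-Smirnov at alpha = 0.01)", {
  m <- rb_model(parameters = list(
    rb_parameter("k", 1e-6, class = "bimolecular_association")))
  ens <- sample_parameters(m, n = 10000, seed = 12, detailed_balance = FALSE)
  v <- log(vapply(ens$sets, `[[`, numeric(1), "k"))
  p <- stats::ks.test(v, "punif", log(1e-7), log(1e-5))$p.value
  expect_gt(p, 0.01)
})

test_that("ensembles are reproducible per seed", {
  m <- build_toy("cycle_binding")
  e1 <- sample_parameters(m, n = 50, seed = 77)
  e2 <- sample_parameters(m, n = 50, seed = 77)
  expect_identical(e1$sets, e2$sets)
  e3 <- sample_parameters(m, n = 50, seed = 78)
  expect_false(identical(e1$sets, e3$sets))
})

test_that("acyclic binding networks need no adjustment", {
  m <- build_toy("chain")   # A-B-C assembly: no thermodynamic cycle
  ps <- sapply(m$parameters, function(p) p$value)
  res <- enforce_detailed_balance(ps, m)
  expect_identical(res$adjusted, character(0))
  expect_length(detailed_balance_audit(ps, m), 0L)
})

test_that("cycle closure resets the dependent dissociation constant", {
  m <- build_toy("cycle_binding")
  # the two association orders around the cycle must satisfy K1*K4 = K3*K2
  ps <- sapply(m$parameters, function(p) p$value)
  ps[["kar1"]] <- 0.01   # K1 = kaf1/kar1 = 1e-4
  ps[["kbr2"]] <- 0.5
  res <- enforce_detailed_balance(ps, m)
  expect_gt(length(res$adjusted), 0L)
  v <- res$values
  K <- function(f, r) v[[f]] / v[[r]]
  lhs <- K("kaf1", "kar1") * K("kbf2", "kbr2")
  rhs <- K("kbf1", "kbr1") * K("kaf2", "kar2")
  expect_lt(abs(lhs / rhs - 1), 1e-9)
  expect_true(all(abs(detailed_balance_audit(v, m) - 1) <= 1e-9))
})

test_that("every sampled set passes an independent cycle audit", {
  m <- build_toy("cycle_binding")
  ens <- sample_parameters(m, n = 100, seed = 9)
  devs <- vapply(ens$sets, function(s)
    max(abs(detailed_balance_audit(s, m) - 1)), numeric(1))
  expect_true(all(devs <= 1e-9))
  # adjusted constants stay inside their class range
  kbr2 <- vapply(ens$sets, `[[`, numeric(1), "kbr2")
  expect_true(all(kbr2 >= 1e-2 & kbr2 <= 1))
})

test_that("concentrations convert to copies via Avogadro and effective volume", {
  expect_identical(convert_concentration(5e-9, compartment("C", 3, 1e-12)), 3011)
  expect_identical(convert_concentration(0, compartment("C", 3, 1e-12)), 0)
  c1 <- convert_concentration(3e-9, compartment("C", 3, 1e-12))
  c2 <- convert_concentration(3e-9, compartment("C", 3, 2e-12))
  expect_lte(abs(c2 - 2 * c1), 1)
  # scale factor multiplies the effective volume
  expect_identical(convert_concentration(5e-9, compartment("C", 3, 1e-12, 0.2)),
                   convert_concentration(1e-9, compartment("C", 3, 1e-12)))
  expect_error(convert_concentration(1e-9, compartment("M", 2, 1)), "3-D")
})

test_that("ensemble export round-trips shape and manifest", {
  m <- build_toy("binding")
  ens <- sample_parameters(m, n = 10, seed = 3)
  path <- file.path(tempdir(), "ens.csv")
  write_ensemble(ens, path)
  df <- utils::read.csv(path)
  expect_identical(dim(df), c(10L, 2L))
  man <- jsonlite::read_json(paste0(path, ".json"))
  expect_identical(man$seed, 3L)
  expect_identical(man$n_sets, 10L)
})
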