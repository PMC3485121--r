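# Exact state-space enumeration: local docking sites, monomers, dimers.

# independent arithmetic oracle: counts complexes without enumerating them
oracle_binder_count <- function(b) {
  total <- 0
  for (ms in b$modification_states) {
    prod_ <- 1
    for (cs in b$child_sites) {
      gate <- cs$gating
      opts <- 1
      if (is.null(gate) || is.na(gate) || identical(gate, ms)) {
        opts <- 1 + sum(vapply(cs$binders, oracle_binder_count, numeric(1)))
      }
      prod_ <- prod_ * opts
    }
    total <- total + prod_
  }
  total
}

oracle_site_count <- function(site) {
  unbound <- if (site$phospho_dependent) 2 else 1
  unbound + sum(vapply(site$binders, oracle_binder_count, numeric(1)))
}

binder_counter <- new.env()
binder_counter$i <- 0L
random_binder <- function(depth, branch) {
  binder_counter$i <- binder_counter$i + 1L   # unique names: dedup-free oracle
  nchild <- if (depth <= 0) 0 else sample(0:branch, 1)
  binder_spec(paste0("M", binder_counter$i),
              modification_states = paste0("s", seq_len(sample(1:2, 1))),
              child_sites = lapply(seq_len(nchild), function(i) {
                list(name = paste0("c", i),
                     binders = lapply(seq_len(sample(1:2, 1)), function(j)
                       random_binder(depth - 1L, branch)),
                     gating = if (runif(1) < 0.4) "s1" else NA)
              }))
}

test_that("canonical docking sites enumerate to 2, 8, 6, 3 states", {
  expect_length(enumerate_site_states(ligand_site_spec("EGF")), 2L)
  shc1 <- enumerate_site_states(shc1_site_spec())
  expect_length(shc1, 8L)
  expect_identical(shc1[1:2], c("unphos", "phos"))
  expect_length(enumerate_site_states(grb2_site_spec()), 6L)
  expect_length(enumerate_site_states(pi3k_site_spec()), 3L)
  # site with no binders and no phospho-dependence has a single state
  expect_length(enumerate_site_states(site_spec("plain")), 1L)
})

test_that("dual-specificity site counting takes the union of bound states", {
  expect_identical(count_dual_site(list(grb2_site_spec("Y"), shc1_site_spec("Y"))),
                   12L)
  # identical specs deduplicate to the single-spec count
  expect_identical(count_dual_site(list(grb2_site_spec("Y"), grb2_site_spec("Y"))),
                   6L)
  # 3-way union equals the brute-force set union
  specs <- list(grb2_site_spec("Y"), shc1_site_spec("Y"), pi3k_site_spec("Y"))
  want <- length(unique(unlist(lapply(specs, enumerate_site_states))))
  expect_identical(count_dual_site(specs), want)
  # unbound-state disagreement is an error
  expect_error(count_dual_site(list(ligand_site_spec(), shc1_site_spec())),
               "unbound")
})

test_that("monomer counts are per-site products; the canonical monomers are exact", {
  expect_identical(count_monomer_states(egfr_state_spec()), 331776)
  expect_identical(count_monomer_states(erbb3_state_spec()), 11664)
  expect_identical(count_monomer_states(molecule_state_spec("empty", list())), 1)
  # product equals the length of the Cartesian product of site state lists
  spec <- molecule_state_spec("X", list(shc1_site_spec("a"), pi3k_site_spec("b"),
                                        ligand_site_spec()))
  grid_len <- prod(vapply(spec$sites, function(s)
    length(enumerate_site_states(s)), numeric(1)))
  expect_identical(count_monomer_states(spec), grid_len)
})

test_that("site enumeration length equals the arithmetic oracle on random specs", {
  set.seed(31)
  for (i in 1:40) {
    s <- site_spec("s", runif(1) < 0.5,
                   binders = lapply(seq_len(sample(1:2, 1)), function(j)
                     random_binder(depth = sample(0:2, 1), branch = 2)))
    expect_identical(length(enumerate_site_states(s)), as.integer(oracle_site_count(s)),
                     info = i)
  }
})

test_that("dimer counts: heterodimers multiply, homodimers pair without order", {
  egfr <- egfr_state_spec(); erbb3 <- erbb3_state_spec()
  expect_identical(count_dimer_states(egfr, erbb3), 3869835264)
  expect_true(count_dimer_states(egfr, erbb3) >= 3.8e9)
  n <- count_monomer_states(egfr)
  expect_identical(count_dimer_states(egfr, egfr), n * (n + 1) / 2)
  expect_identical(count_dimer_states(egfr, egfr), 55037822976)
  expect_true(count_dimer_states(egfr, egfr) >= 5.5e10)
  # n = 1 homodimer
  one <- molecule_state_spec("solo", list(site_spec("p")))
  expect_identical(count_dimer_states(one, one), 1)
  # exactness property on random sizes: (n^2 + n) / 2 with integer arithmetic
  for (k in c(3, 7, 12)) {
    sp <- molecule_state_spec("Z", rep(list(pi3k_site_spec("q")), k))
    n <- count_monomer_states(sp)
    expect_identical(count_dimer_states(sp, sp), (n^2 + n) / 2)
  }
})

test_that("counts beyond exact double-integer range abort rather than round", {
  big <- molecule_state_spec("big", rep(list(shc1_site_spec("y")), 60))
  expect_error(count_monomer_states(big), "exactly representable")
})
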