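# On-the-fly simulator: lazy expansion, census semantics, equivalence of
# lazy and eager enumeration, agreement with the network-free engine.

eager_expand <- function(model, cap = 500L) {
  crm <- rbnet:::compile_run_model(model)
  net <- rbnet:::otf_new_network(model, crm, cap)
  for (s in model$seed_species) {
    cs <- rbnet:::compile_species(s$species, crm$reg)
    si <- rbnet:::otf_add_species(net, cs)
    net$pop[si] <- net$pop[si] + s$copies
  }
  repeat {
    todo <- which(!net$expanded[seq_along(net$species)])
    if (!length(todo) || net$capped) break
    for (si in todo) rbnet:::otf_expand_species(net, crm, si)
  }
  net
}

test_that("expanding free A under the binding rule yields A.B and one channel", {
  m <- build_toy("binding", copies = 10)
  crm <- rbnet:::compile_run_model(m)
  net <- rbnet:::otf_new_network(m, crm, 100L)
  for (s in m$seed_species) {
    cs <- rbnet:::compile_species(s$species, crm$reg)
    si <- rbnet:::otf_add_species(net, cs)
    net$pop[si] <- net$pop[si] + 10
  }
  rbnet:::otf_expand_species(net, crm, 1L)
  rbnet:::otf_expand_species(net, crm, 2L)
  expect_identical(length(net$species), 3L)   # A, B, A.B
  expect_identical(length(net$c0), 1L)        # forward binding only
  # idempotent
  before <- length(net$c0)
  rbnet:::otf_expand_species(net, crm, 1L)
  expect_identical(length(net$c0), before)
})

test_that("lazy expansion run to exhaustion equals eager full enumeration", {
  # 3-site receptor: exactly 2^3 = 8 phosphoforms, 24 reactions
  net <- eager_expand(build_toy("multisite_phospho", copies = 5))
  expect_identical(length(net$species), 8L)
  expect_identical(length(net$c0), 24L)
  expect_false(net$capped)
  # chain A-B-C: 6 species
  net2 <- eager_expand(build_toy("chain", copies = 5))
  expect_identical(length(net2$species), 6L)
  # binding: 3 species and 2 reactions
  net3 <- eager_expand(build_toy("binding", copies = 5))
  expect_identical(length(net3$species), 3L)
  expect_identical(length(net3$c0), 2L)
})

test_that("the census counts populated species exactly", {
  m <- build_toy("binding", copies = 40)
  res <- simulate_onthefly(m, t_end = 30, sample_dt = 10, seed = 8)
  expect_identical(res$census$populated_species[1], 2L)     # A and B at t=0
  expect_identical(max(res$census$populated_species), 3L)   # A, B, AB
  expect_true(all(res$census$total_species_generated <= 3L))
  # census never exceeds generated species
  expect_true(all(res$census$populated_species <=
                  res$census$total_species_generated))
})

test_that("network cap triggers a graceful, flagged partial result", {
  m <- build_erbb_mini(1)
  pro <- sim_protocol(additions = list(
    list(species = "EGF(r)", conc = 5e-9, compartment = "Ex"),
    list(species = "HRG(r)", conc = 5e-9, compartment = "Ex")))
  res <- simulate_onthefly(m, protocol = pro, t_end = 6, sample_dt = 2,
                           seed = 7, scale = 0.01, max_species = 120)
  expect_true(res$trajectory$metadata$capped)
  expect_identical(res$trajectory$metadata$species_generated, 120L)
})

test_that("on-the-fly means agree with network-free means on the isomerization toy", {
  m <- build_toy("isomerization", copies = 60)
  nf <- sapply(1:60, function(s)
    simulate_network_free(m, t_end = 20, sample_dt = 10, seed = s)$values[, "Ap"])
  ot <- sapply(1:60, function(s)
    simulate_onthefly(m, t_end = 20, sample_dt = 10, seed = 500 + s)$trajectory$values[, "Ap"])
  se <- sqrt(apply(nf, 1, var) / ncol(nf) + apply(ot, 1, var) / ncol(ot))
  gap <- abs(rowMeans(nf) - rowMeans(ot))
  expect_true(all(gap[-1] <= 3 * se[-1]))
  # symmetric rates: long-time occupancy 1/2
  expect_lt(abs(mean(nf[3, ]) / 60 - 0.5), 0.05)
})

test_that("census and network exports are well-formed", {
  m <- build_toy("binding", copies = 20)
  res <- simulate_onthefly(m, t_end = 10, sample_dt = 5, seed = 2)
  cpath <- file.path(tempdir(), "census.csv")
  write_census(res$census, cpath)
  expect_identical(names(utils::read.csv(cpath)),
                   c("time", "populated_species", "ever_populated_species",
                     "total_species_generated", "total_reactions_generated"))
  npath <- file.path(tempdir(), "network.json")
  write_network(res$network, npath)
  js <- jsonlite::read_json(npath)
  expect_identical(length(js$species), 3L)
})
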