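# Network-free particle simulator: initialization, rate law arithmetic,
# stepping, conservation, reproducibility, incremental-index integrity.

nf_state_for <- function(model, scale = 1) {
  crm <- rbnet:::compile_run_model(model)
  st <- rbnet:::nf_new_state(model, crm)
  for (s in model$seed_species) {
    cs <- rbnet:::compile_species(s$species, crm$reg)
    rbnet:::nf_add_species(st, cs, round(rbnet:::seed_copy_number(s, model) * scale))
  }
  rbnet:::nf_index_all(st)
  st
}

test_that("initialization instantiates seeds and the embedding index", {
  m <- build_toy("binding", copies = 100)
  st <- nf_state_for(m)
  expect_identical(sum(st$typ > 0L), 200L)
  # pattern A(b) has one embedding per free A
  j <- st$entry_of_rule[1, 1]
  expect_identical(rbnet:::entry_count(st, j), 100L)
  # empty seed block: zero particles, total rate zero
  m0 <- rb_model(molecule_types = m$molecule_types,
                 parameters = m$parameters, rules = m$rules)
  st0 <- nf_state_for(m0)
  expect_identical(sum(st0$typ > 0L), 0L)
  expect_identical(sum(rbnet:::nf_rates(st0)), 0)
})

test_that("seed scaling multiplies copy numbers with round-half-to-even", {
  m <- build_toy("binding", copies = 125)
  st <- nf_state_for(m, scale = 0.2)   # 125 * 0.2 = 25
  expect_identical(sum(st$typ == 1L), 25L)
  expect_identical(round(0.5), 0)      # banker's rounding underlies the rule
})

test_that("total rate follows mass-action arithmetic with symmetry factors", {
  # unimolecular: k = 0.1, 50 matches -> 5.0 s^-1
  m1 <- build_toy("isomerization", copies = 50)
  m1$parameters[["kf"]]$value <- 0.1
  m1$parameters[["kr"]]$value <- 0.2
  st1 <- nf_state_for(m1)
  expect_equal(rbnet:::nf_rates(st1), c(0.1 * 50, 0))

  # bimolecular A+B: k = 1e-6, 100 x 200 -> 0.02 s^-1
  m2 <- build_toy("binding")
  m2$parameters[["kon"]]$value <- 1e-6
  m2$seed_species[[1]]$copies <- 100
  m2$seed_species[[2]]$copies <- 200
  st2 <- nf_state_for(m2)
  expect_equal(rbnet:::nf_rates(st2)[1], 1e-6 * 100 * 200)

  # A+A dimerization: 10 free A, k = 1e-6 -> 10*9/2 * 1e-6 = 4.5e-5 s^-1
  m3 <- build_toy("dimerization", copies = 10)
  m3$parameters[["kon"]]$value <- 1e-6
  st3 <- nf_state_for(m3)
  expect_equal(rbnet:::nf_rates(st3)[1], 4.5e-5)
})

test_that("irreversible binding exhausts the limiting reactant", {
  m <- rb_model(
    molecule_types = list(molecule_type("A", "b"), molecule_type("B", "a")),
    parameters = list(rb_parameter("kon", 10)),
    seed_species = list(list(species = "A(b)", copies = 30),
                        list(species = "B(a)", copies = 17)),
    rules = list(rb_rule("bind", list("A(b)", "B(a)"),
                         list("A(b!1).B(a!1)"), "kon")),
    observables = list(rb_observable("AB", "Molecules", "A(b!+)")))
  tr <- simulate_network_free(m, t_end = 10, sample_dt = 10, seed = 11)
  expect_identical(tr$values[nrow(tr$values), "AB"][[1]], 17)
})

test_that("waiting times of a constant-rate system are exponential", {
  m <- build_toy("isomerization", copies = 100)  # total rate 0.1*n constant
  st <- nf_state_for(m)
  set.seed(99)
  dts <- vapply(1:4000, function(i) rbnet:::nf_step(st)$dt, numeric(1))
  rate <- 0.1 * 100
  se <- (1 / rate) / sqrt(length(dts))
  expect_lt(abs(mean(dts) - 1 / rate), 3 * se)
})

test_that("per-type molecule counts are conserved without create/delete rules", {
  m <- build_toy("chain", copies = 30)
  st <- nf_state_for(m)
  counts0 <- table(st$typ[st$typ > 0L])
  set.seed(5)
  for (i in 1:500) rbnet:::nf_step(st)
  expect_identical(table(st$typ[st$typ > 0L]), counts0)
})

test_that("the incremental embedding index equals a full recomputation", {
  for (toy in c("chain", "dimerization", "multisite_phospho")) {
    m <- build_toy(toy, copies = 40)
    st <- nf_state_for(m)
    set.seed(7)
    for (i in 1:800) rbnet:::nf_step(st)
    expect_true(rbnet:::nf_check_index(st), info = toy)
  }
})

test_that("identical (model, protocol, seed) gives identical trajectories", {
  m <- build_toy("binding", copies = 60)
  pro <- sim_protocol(equilibrate = 5,
                      additions = list(list(species = "A(b)", copies = 10)))
  t1 <- simulate_network_free(m, protocol = pro, t_end = 20, sample_dt = 5, seed = 42)
  t2 <- simulate_network_free(m, protocol = pro, t_end = 20, sample_dt = 5, seed = 42)
  expect_identical(t1$values, t2$values)
  t3 <- simulate_network_free(m, protocol = pro, t_end = 20, sample_dt = 5, seed = 43)
  expect_false(identical(t3$values, t1$values))
})

test_that("observables distinguish Molecules and Species semantics", {
  m <- build_toy("dimerization", copies = 20)
  tr <- simulate_network_free(m, t_end = 30, sample_dt = 30, seed = 3)
  # at any time: free A + 2 * dimers = 20
  final <- tr$values[nrow(tr$values), ]
  expect_identical(final[["A_free"]] + 2 * final[["AA"]], 20)
})

test_that("trajectory export writes CSV plus JSON sidecar", {
  m <- build_toy("binding", copies = 30)
  tr <- simulate_network_free(m, t_end = 10, sample_dt = 5, seed = 1)
  path <- file.path(tempdir(), "traj.csv")
  write_trajectory(tr, path)
  df <- utils::read.csv(path, check.names = FALSE)
  expect_identical(names(df), c("time", "AB", "A_free"))
  expect_equal(df$time, tr$times)
  meta <- jsonlite::read_json(paste0(path, ".json"))
  expect_identical(meta$method, "network_free")
  expect_identical(meta$seed, 1L)
})
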