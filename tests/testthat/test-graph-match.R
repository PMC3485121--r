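# Pattern matching, symmetry counting, canonical labels, connectivity.

mt_model <- function() {
  rb_model(molecule_types = list(
    molecule_type("A", "b"), molecule_type("B", "a"),
    molecule_type("S", "x", "x", "x"),
    molecule_type("R", "y1~U~P", "y2~U~P")))
}

test_that("embedding counts on canonical examples", {
  m <- mt_model()
  # 10 free monomers -> 10 embeddings
  targets <- replicate(10, parse_pattern("A(b)"), simplify = FALSE)
  expect_length(find_embeddings("A(b)", targets, m), 10L)
  # homodimer pattern embeds twice into one homodimer (swap symmetry)
  mm <- rb_model(molecule_types = list(molecule_type("A", "b")))
  expect_length(find_embeddings("A(b!1).A(b!1)", "A(b!1).A(b!1)", mm), 2L)
})

test_that("automorphism counts: asymmetric dimer 1, homodimer 2, 3-arm star 6", {
  m <- mt_model()
  expect_identical(count_automorphisms("A(b!1).B(a!1)", m), 1L)
  mm <- rb_model(molecule_types = list(molecule_type("A", "b")))
  expect_identical(count_automorphisms("A(b!1).A(b!1)", mm), 2L)
  star <- "S(x!1,x!2,x!3).B(a!1).B(a!2).B(a!3)"
  expect_identical(count_automorphisms(star, m), 6L)
})

test_that("embedding enumeration equals the brute-force oracle on random instances", {
  set.seed(101)
  m <- oracle_types_model()
  n_checked <- 0L
  while (n_checked < 120L) {
    p <- random_pattern_sg(sample(1:3, 1L), m)
    if (is.null(p)) next
    t <- random_species_sg(sample(1:6, 1L), m)
    got <- length(find_embeddings(p, t, m))
    want <- oracle_embedding_count(p, t)
    expect_identical(got, want,
                     info = paste("pattern", format(p), "target", format(t)))
    n_checked <- n_checked + 1L
  }
})

test_that("canonical labels are isomorphism-invariant and collision-free", {
  m <- oracle_types_model()
  # construction order does not matter
  mm <- mt_model()
  l1 <- canonical_label("A(b!1).B(a!1)", mm)
  l2 <- canonical_label("B(a!5).A(b!5)", mm)
  expect_identical(l1, l2)
  # distinct phosphoforms get distinct labels
  expect_false(canonical_label("R(y1~P,y2~U)", mm) ==
               canonical_label("R(y1~U,y2~P)", mm))

  set.seed(202)
  species <- list()
  labels <- character(0)
  n <- 0L
  while (n < 150L) {
    s <- random_species_sg(sample(1:5, 1L), m)
    comps <- connected_components(s)
    s <- comps[[which.max(vapply(comps, function(g) length(g$mols), integer(1)))]]
    lab <- canonical_label(s, m)
    # isomorphic shuffle must map to the same label
    expect_identical(canonical_label(shuffled_copy(s), m), lab)
    # equality of labels must coincide with brute-force isomorphism
    if (length(species)) {
      j <- sample.int(length(species), 1L)
      expect_identical(lab == labels[j], oracle_isomorphic(s, species[[j]]),
                       info = paste(lab, "vs", labels[j]))
    }
    species[[length(species) + 1L]] <- s
    labels <- c(labels, lab)
    n <- n + 1L
  }
})

test_that("canonical labels reject wildcards", {
  expect_error(canonical_label("R(y1~P!?)", mt_model()), "concrete")
})

test_that("connected components partition by bond connectivity", {
  g <- parse_pattern("A(b!1).B(a!1).A(b)")
  cc <- connected_components(g)
  expect_length(cc, 2L)
  expect_length(cc[[1]]$mols, 2L)
  # random graphs: component count agrees with a union-find over bond labels
  set.seed(303)
  for (i in 1:25) {
    s <- random_species_sg(sample(2:6, 1L))
    cc <- connected_components(s)
    # oracle: count via label co-occurrence closure
    n <- length(s$mols)
    adj <- matrix(FALSE, n, n)
    ends <- sg_bond_ends(s)
    for (e in ends) adj[e[[1]][1], e[[2]][1]] <- adj[e[[2]][1], e[[1]][1]] <- TRUE
    seen <- logical(n); ncomp <- 0L
    for (v in seq_len(n)) {
      if (seen[v]) next
      ncomp <- ncomp + 1L
      q <- v
      while (length(q)) {
        cur <- q[1]; q <- q[-1]
        if (seen[cur]) next
        seen[cur] <- TRUE
        q <- c(q, which(adj[cur, ] & !seen))
      }
    }
    expect_length(cc, ncomp)
    expect_identical(sum(vapply(cc, function(g) length(g$mols), integer(1))), n)
  }
})
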