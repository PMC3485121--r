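# Time-course normalization, clustering, contact maps, exports.

test_that("max-normalization follows the heat-map convention", {
  m <- rbind(a = c(0, 2, 4), b = c(0, 0, 0))
  nm <- normalize_timecourses(m)
  expect_equal(nm["a", ], c(0, 0.5, 1))
  expect_equal(nm["b", ], c(0, 0, 0))
  expect_identical(attr(nm, "zero_rows"), 2L)
  # idempotent
  expect_equal(normalize_timecourses(nm)["a", ], nm["a", ])
})

test_that("identical rows merge first; constant rows are segregated", {
  m <- rbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8), c = c(4, 3, 2, 1),
             k = c(5, 5, 5, 5))
  cl <- cluster_timecourses(m)
  expect_identical(cl$constant_rows, 4L)
  expect_equal(cl$heights[1], 0)             # rows a,b are perfectly correlated
  expect_identical(sort(cl$order), 1:4)
  expect_identical(cl$order[4], 4L)          # constant row appended last
})

test_that("average-linkage heights match the stats::hclust oracle", {
  set.seed(11)
  for (i in 1:60) {
    n <- sample(3:20, 1)
    m <- matrix(runif(n * 10), n, 10)
    rownames(m) <- paste0("r", seq_len(n))
    cl <- cluster_timecourses(m)
    hc <- stats::hclust(stats::as.dist(1 - stats::cor(t(m))), method = "average")
    expect_equal(sort(cl$tree$height), sort(hc$height), tolerance = 1e-10)
    expect_equal(as.matrix(stats::cophenetic(cl$tree)),
                 as.matrix(stats::cophenetic(hc))[cl$tree$labels, cl$tree$labels],
                 tolerance = 1e-10)
  }
})

test_that("the tree is stable under input row permutation", {
  set.seed(21)
  m <- matrix(runif(8 * 12), 8, 12)
  rownames(m) <- paste0("r", 1:8)
  cl <- cluster_timecourses(m)
  for (i in 1:5) {
    perm <- sample(8)
    clp <- cluster_timecourses(m[perm, ])
    co1 <- as.matrix(stats::cophenetic(cl$tree))
    co2 <- as.matrix(stats::cophenetic(clp$tree))
    expect_equal(co2[rownames(co1), colnames(co1)], co1, tolerance = 1e-10)
  }
})

test_that("contact maps cover every rule and collapse contextual refinements", {
  # toy binding: exactly one edge, both rule directions attached
  cm <- extract_contact_map(build_toy("binding"))
  expect_identical(nrow(cm$binding_edges), 1L)
  expect_identical(cm$binding_edges$multiplicity, 2L)

  # three contextual refinements of one interaction -> one edge, multiplicity 3
  m3 <- rb_model(
    molecule_types = list(molecule_type("R", "a", "b", "c"),
                          molecule_type("L", "r")),
    parameters = list(rb_parameter("k", 1)),
    rules = list(
      rb_rule("r1", list("R(a,b)", "L(r)"), list("R(a!1,b).L(r!1)"), "k"),
      rb_rule("r2", list("R(a,b!+)", "L(r)"), list("R(a!1,b!+).L(r!1)"), "k"),
      rb_rule("r3", list("R(a,c!+)", "L(r)"), list("R(a!1,c!+).L(r!1)"), "k")))
  cm3 <- extract_contact_map(m3)
  expect_identical(nrow(cm3$binding_edges), 1L)
  expect_identical(cm3$binding_edges$multiplicity, 3L)

  # reduced ERBB model: edge set equals the authored manifest
  m <- build_erbb_mini(1)
  cm1 <- extract_contact_map(m)
  got <- sort(paste(cm1$binding_edges$from, cm1$binding_edges$to, sep = "--"))
  want <- sort(vapply(attr(m, "manifest")$binding_edges, function(e)
    paste(sort(e), collapse = "--"), character(1)))
  expect_identical(got, want)
  # receptor kinase arrows present
  cm2 <- extract_contact_map(build_erbb_mini(2))
  expect_true(all(c("SOS1", "RAS", "RAF", "MEK", "ERK", "PI3K") %in%
                  cm2$enzyme_edges$enzyme))
  # coverage: mapped + unmapped account for every rule
  expect_identical(length(cm2$mapped) + length(cm2$unmapped),
                   length(build_erbb_mini(2)$rules))
  expect_true(all(grepl("^dp_", cm2$unmapped)))
})

test_that("exports are well-formed and byte-deterministic", {
  cm <- extract_contact_map(build_erbb_mini(1))
  p1 <- file.path(tempdir(), "cm1.graphml")
  p2 <- file.path(tempdir(), "cm2.graphml")
  write_contact_map(cm, p1, "graphml")
  write_contact_map(cm, p2, "graphml")
  expect_identical(readLines(p1), readLines(p2))
  doc <- xml2::read_xml(p1)
  expect_identical(xml2::xml_name(doc), "graphml")
  expect_identical(length(xml2::xml_find_all(doc, ".//d1:node",
                                             xml2::xml_ns(doc))),
                   length(cm$nodes))
  pd <- file.path(tempdir(), "cm.dot")
  write_contact_map(cm, pd, "dot")
  expect_match(readLines(pd)[1], "^graph")
  pj <- file.path(tempdir(), "cm.json")
  write_contact_map(cm, pj, "json")
  js <- jsonlite::read_json(pj)
  expect_identical(length(js$nodes), length(cm$nodes))

  # matrix CSV round trip is lossless
  m <- matrix(c(0, 0.25, 1, 0.5), 2, 2,
              dimnames = list(c("s1", "s2"), c("0", "10")))
  pm <- file.path(tempdir(), "tc.csv")
  write_timecourses(m, pm)
  expect_equal(read_timecourses(pm), m)
})

test_that("trajectories convert to observable x time matrices", {
  tr <- simulate_network_free(build_toy("binding", copies = 30),
                              t_end = 10, sample_dt = 5, seed = 2)
  m <- timecourse_matrix(tr)
  expect_identical(dim(m), c(2L, 3L))
  expect_identical(rownames(m), c("AB", "A_free"))
})
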