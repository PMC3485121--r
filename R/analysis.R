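# Post-simulation analysis: max-normalization and average-linkage Pearson
# clustering of phosphorylation time courses, and model-level contact-map
# extraction.

#' Build an observable x time matrix from trajectories
#'
#' @param traj an `rb_trajectory` (or list of them; rows are concatenated).
#' @return numeric matrix, rows = observables, columns = sample times.
#' @export
timecourse_matrix <- function(traj) {
  if (inherits(traj, "rb_trajectory")) traj <- list(traj)
  mats <- lapply(traj, function(tr) {
    m <- t(tr$values)
    colnames(m) <- tr$times
    m
  })
  do.call(rbind, mats)
}

#' Max-normalize time courses
#'
#' Divides each row by its own maximum, the convention used for
#' phosphorylation heat maps; all-zero rows are left at zero and flagged in
#' the `zero_rows` attribute. Idempotent.
#'
#' @param m nonnegative matrix, rows = observables.
#' @return normalized matrix with attribute `zero_rows` (row indices).
#' @export
normalize_timecourses <- function(m) {
  stopifnot(is.matrix(m), all(m >= 0))
  mx <- apply(m, 1L, max)
  zero <- which(mx == 0)
  mx[mx == 0] <- 1
  out <- m / mx
  attr(out, "zero_rows") <- unname(zero)
  out
}

#' Hierarchical clustering of normalized time courses
#'
#' Agglomerative average-linkage clustering under the distance
#' 1 - Pearson correlation between rows, with deterministic tie-breaking
#' (among equally close pairs, the one containing the lowest original row
#' index merges first, then the lowest second index). Constant rows, for
#' which Pearson correlation is undefined, are segregated before clustering
#' and appended at the end of the ordering.
#'
#' @param m numeric matrix, rows = observables (use
#'   [normalize_timecourses()] first for the heat-map convention).
#' @return list: `order` (row ordering, left-to-right leaf order followed by
#'   constant rows), `tree` (an object of class `hclust` over the
#'   clusterable rows), `constant_rows` (indices), `heights`.
#' @export
cluster_timecourses <- function(m) {
  n_all <- nrow(m)
  if (is.null(rownames(m))) rownames(m) <- paste0("row", seq_len(n_all))
  const <- which(apply(m, 1L, function(x) stats::sd(x) == 0 || !is.finite(stats::sd(x))))
  keep <- setdiff(seq_len(n_all), const)
  if (length(keep) < 2L) {
    warning("fewer than 2 clusterable rows; identity ordering returned")
    return(list(order = seq_len(n_all), tree = NULL,
                constant_rows = unname(const), heights = numeric(0)))
  }
  D <- 1 - stats::cor(t(m[keep, , drop = FALSE]))
  n <- length(keep)
  # active clusters: id > 0 = merged cluster index, id < 0 = singleton -row
  active <- as.list(-seq_len(n))
  sizes <- rep(1L, n)
  reps <- seq_len(n)       # lowest original member index per cluster
  d <- D
  diag(d) <- Inf
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  node_of <- -seq_len(n)   # hclust node id per active slot
  alive <- rep(TRUE, n)
  for (step in seq_len(n - 1L)) {
    idx <- which(alive)
    dm <- d[idx, idx, drop = FALSE]
    mn <- min(dm)
    cand <- which(dm <= mn + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    # deterministic tie rule on original row indices
    key <- cbind(pmin(reps[idx[cand[, 1]]], reps[idx[cand[, 2]]]),
                 pmax(reps[idx[cand[, 1]]], reps[idx[cand[, 2]]]))
    pick <- order(key[, 1], key[, 2])[1]
    a <- idx[cand[pick, 1]]; b <- idx[cand[pick, 2]]
    if (reps[a] > reps[b]) { tmp <- a; a <- b; b <- tmp }
    merge[step, ] <- sort(c(node_of[a], node_of[b]))
    height[step] <- d[a, b]
    # average linkage update into slot a
    others <- setdiff(which(alive), c(a, b))
    if (length(others)) {
      d[a, others] <- (sizes[a] * d[a, others] + sizes[b] * d[b, others]) /
        (sizes[a] + sizes[b])
      d[others, a] <- d[a, others]
    }
    sizes[a] <- sizes[a] + sizes[b]
    reps[a] <- min(reps[a], reps[b])
    alive[b] <- FALSE
    d[b, ] <- Inf; d[, b] <- Inf
    node_of[a] <- step
  }
  # leaf order: left-to-right traversal
  leaf_order <- function(node) {
    if (node < 0L) return(-node)
    c(leaf_order(merge[node, 1]), leaf_order(merge[node, 2]))
  }
  ord_local <- leaf_order(n - 1L)
  tree <- structure(list(merge = merge, height = height, order = ord_local,
                         labels = rownames(m)[keep], method = "average",
                         dist.method = "1-pearson",
                         call = match.call()),
                    class = "hclust")
  list(order = unname(c(keep[ord_local], const)), tree = tree,
       constant_rows = unname(const), heights = height)
}

# --- contact maps ------------------------------------------------------------

#' Extract a machine-readable contact map from a model
#'
#' Produces the structural summary an extended contact map draws: proteins
#' with nested components and modification flags, undirected binding edges
#' (one per distinct component pair appearing in any bond-forming rule, with
#' the number of contextual rule refinements as multiplicity), and directed
#' enzyme-substrate edges for state-change rules. The enzyme is the
#' reactant-pattern molecule other than the substrate when exactly one
#' exists; otherwise an explicit `@enzyme=Name` suffix on the rule name is
#' honored. Rules contributing to no edge (transport, degradation,
#' uncatalyzed state changes) are listed as unmapped, so every rule is
#' accounted for.
#'
#' @param model an [rb_model()].
#' @return object of class `contact_map`: `nodes`, `binding_edges`,
#'   `enzyme_edges`, `unmapped`.
#' @export
extract_contact_map <- function(model) {
  nodes <- lapply(model$molecule_types, function(mt) {
    list(name = mt$name, compartment = mt$compartment,
         components = lapply(mt$comps, function(cc)
           list(name = cc$name, flags = cc$states)))
  })
  bind_edges <- list()
  enz_edges <- list()
  mapped <- character(0)
  unmapped <- character(0)
  edge_key <- function(a, b) paste(sort(c(a, b)), collapse = " -- ")
  for (r in model$rules) {
    tfs <- derive_transformations(r)
    kinds <- vapply(tfs, `[[`, character(1), "kind")
    hit <- FALSE
    side <- r$reactants
    # bond-forming (and its reverse bond-breaking) rules -> binding edges
    for (t in tfs[kinds %in% c("AddBond", "DeleteBond")]) {
      ep <- function(ref, which_side) {
        if (identical(ref[1], "new")) {
          # endpoint on a created molecule: locate in products
          pf <- flatten_side(r$products)
          created <- pf[[as.integer(ref[2])]]
          m <- created$m
          c(m$type, m$comps[[as.integer(ref[3])]]$name)
        } else {
          ref <- as.integer(ref)
          m <- side[[ref[1]]]$mols[[ref[2]]]
          c(m$type, m$comps[[ref[3]]]$name)
        }
      }
      e1 <- ep(t$ref1); e2 <- ep(t$ref2)
      a <- paste0(e1[1], ".", e1[2]); b <- paste0(e2[1], ".", e2[2])
      k <- edge_key(a, b)
      if (is.null(bind_edges[[k]])) {
        bind_edges[[k]] <- list(a = min(a, b), b = max(a, b),
                                rules = character(0))
      }
      bind_edges[[k]]$rules <- c(bind_edges[[k]]$rules, r$name)
      hit <- TRUE
    }
    # catalyzed state changes -> enzyme-substrate edges
    cs <- tfs[kinds == "ChangeState"]
    if (length(cs)) {
      explicit <- regmatches(r$name,
                             regexec("@enzyme=([A-Za-z0-9_]+)", r$name))[[1]]
      for (t in cs) {
        ref <- as.integer(t$ref)
        sub_mol <- side[[ref[1]]]$mols[[ref[2]]]
        comp <- sub_mol$comps[[ref[3]]]$name
        others <- unlist(lapply(seq_along(side), function(p)
          vapply(seq_along(side[[p]]$mols), function(j) {
            if (p == ref[1] && j == ref[2]) NA_character_
            else side[[p]]$mols[[j]]$type
          }, character(1))))
        others <- others[!is.na(others)]
        bound_ctx <- any(vapply(sub_mol$comps, function(cc)
          cc$bond == "+" || !cc$bond %in% c("0", "?"), logical(1)))
        enzyme <- if (length(explicit)) explicit[2]
                  else if (length(others) == 1L) others
                  else NA_character_
        if (!is.na(enzyme) && (length(others) >= 1L || bound_ctx)) {
          k <- paste0(enzyme, " -> ", sub_mol$type, ".", comp, "~", t$state)
          if (is.null(enz_edges[[k]])) {
            enz_edges[[k]] <- list(enzyme = enzyme, substrate = sub_mol$type,
                                   component = comp, state = t$state,
                                   rules = character(0))
          }
          enz_edges[[k]]$rules <- c(enz_edges[[k]]$rules, r$name)
          hit <- TRUE
        }
      }
    }
    if (hit) mapped <- c(mapped, r$name) else unmapped <- c(unmapped, r$name)
  }
  be <- if (length(bind_edges)) {
    ord <- order(names(bind_edges))
    data.frame(
      from = vapply(bind_edges[ord], `[[`, character(1), "a"),
      to = vapply(bind_edges[ord], `[[`, character(1), "b"),
      multiplicity = vapply(bind_edges[ord], function(e)
        length(unique(e$rules)), integer(1)),
      rules = vapply(bind_edges[ord], function(e)
        paste(sort(unique(e$rules)), collapse = ";"), character(1)),
      row.names = NULL, stringsAsFactors = FALSE)
  } else data.frame(from = character(0), to = character(0),
                    multiplicity = integer(0), rules = character(0))
  ee <- if (length(enz_edges)) {
    ord <- order(names(enz_edges))
    data.frame(
      enzyme = vapply(enz_edges[ord], `[[`, character(1), "enzyme"),
      substrate = vapply(enz_edges[ord], `[[`, character(1), "substrate"),
      component = vapply(enz_edges[ord], `[[`, character(1), "component"),
      state = vapply(enz_edges[ord], `[[`, character(1), "state"),
      multiplicity = vapply(enz_edges[ord], function(e)
        length(unique(e$rules)), integer(1)),
      rules = vapply(enz_edges[ord], function(e)
        paste(sort(unique(e$rules)), collapse = ";"), character(1)),
      row.names = NULL, stringsAsFactors = FALSE)
  } else data.frame(enzyme = character(0), substrate = character(0),
                    component = character(0), state = character(0),
                    multiplicity = integer(0), rules = character(0))
  structure(list(nodes = nodes, binding_edges = be, enzyme_edges = ee,
                 mapped = unique(mapped), unmapped = unmapped),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat("<contact_map> ", length(x$nodes), " proteins, ",
      nrow(x$binding_edges), " binding edges, ",
      nrow(x$enzyme_edges), " enzyme-substrate edges, ",
      length(x$unmapped), " unmapped rules\n", sep = "")
  invisible(x)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Export a contact map
#'
#' Deterministic writers for GraphML (schema-conformant), DOT and JSON.
#'
#' @param map a `contact_map`.
#' @param path output file path.
#' @param format `"graphml"`, `"dot"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_contact_map <- function(map, path, format = c("graphml", "dot", "json")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(list(nodes = map$nodes,
                              binding_edges = map$binding_edges,
                              enzyme_edges = map$enzyme_edges,
                              unmapped = map$unmapped),
                         path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(path))
  }
  protein_of <- function(comp_id) sub("\\..*$", "", comp_id)
  if (format == "graphml") {
    lines <- c(
      '<?xml version="1.0" encoding="UTF-8"?>',
      '<graphml xmlns="http://graphml.graphdrawing.org/xmlns"',
      '         xmlns:xsi="http://www.w3.org/2001/XMLSchema-instance"',
      '         xsi:schemaLocation="http://graphml.graphdrawing.org/xmlns http://graphml.graphdrawing.org/xmlns/1.0/graphml.xsd">',
      '  <key id="kind" for="edge" attr.name="kind" attr.type="string"/>',
      '  <key id="multiplicity" for="edge" attr.name="multiplicity" attr.type="int"/>',
      '  <key id="compartment" for="node" attr.name="compartment" attr.type="string"/>',
      '  <graph id="contact_map" edgedefault="undirected">')
    for (nd in map$nodes) {
      lines <- c(lines, sprintf('    <node id="%s"><data key="compartment">%s</data></node>',
                                xml_escape(nd$name), xml_escape(nd$compartment)))
    }
    eid <- 0L
    for (i in seq_len(nrow(map$binding_edges))) {
      eid <- eid + 1L
      lines <- c(lines, sprintf(
        '    <edge id="e%d" source="%s" target="%s"><data key="kind">binding:%s</data><data key="multiplicity">%d</data></edge>',
        eid, xml_escape(protein_of(map$binding_edges$from[i])),
        xml_escape(protein_of(map$binding_edges$to[i])),
        xml_escape(paste(map$binding_edges$from[i], map$binding_edges$to[i],
                         sep = "--")),
        map$binding_edges$multiplicity[i]))
    }
    for (i in seq_len(nrow(map$enzyme_edges))) {
      eid <- eid + 1L
      lines <- c(lines, sprintf(
        '    <edge id="e%d" source="%s" target="%s" directed="true"><data key="kind">enzyme:%s~%s</data><data key="multiplicity">%d</data></edge>',
        eid, xml_escape(map$enzyme_edges$enzyme[i]),
        xml_escape(map$enzyme_edges$substrate[i]),
        xml_escape(paste0(map$enzyme_edges$substrate[i], ".",
                          map$enzyme_edges$component[i])),
        xml_escape(map$enzyme_edges$state[i]),
        map$enzyme_edges$multiplicity[i]))
    }
    lines <- c(lines, "  </graph>", "</graphml>")
    writeLines(lines, path)
    return(invisible(path))
  }
  # DOT
  lines <- c("graph contact_map {")
  for (nd in map$nodes) {
    lines <- c(lines, sprintf('  "%s" [compartment="%s"];', nd$name,
                              nd$compartment))
  }
  for (i in seq_len(nrow(map$binding_edges))) {
    lines <- c(lines, sprintf('  "%s" -- "%s" [label="%s", multiplicity=%d];',
                              protein_of(map$binding_edges$from[i]),
                              protein_of(map$binding_edges$to[i]),
                              paste(map$binding_edges$from[i],
                                    map$binding_edges$to[i], sep = "--"),
                              map$binding_edges$multiplicity[i]))
  }
  for (i in seq_len(nrow(map$enzyme_edges))) {
    lines <- c(lines, sprintf('  "%s" -- "%s" [dir=forward, label="%s.%s~%s"];',
                              map$enzyme_edges$enzyme[i],
                              map$enzyme_edges$substrate[i],
                              map$enzyme_edges$substrate[i],
                              map$enzyme_edges$component[i],
                              map$enzyme_edges$state[i]))
  }
  lines <- c(lines, "}")
  writeLines(lines, path)
  invisible(path)
}

#' Export a time-course matrix
#'
#' @param m matrix (rows = observables, columns = times).
#' @param path output path.
#' @param format `"csv"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_timecourses <- function(m, path, format = c("csv", "tsv")) {
  format <- match.arg(format)
  df <- data.frame(observable = rownames(m), m, check.names = FALSE)
  if (format == "csv") {
    write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    utils::write.table(df, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  invisible(path)
}

#' Read a time-course matrix written by [write_timecourses()]
#'
#' @param path CSV/TSV path.
#' @return matrix with observable row names.
#' @export
read_timecourses <- function(path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
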