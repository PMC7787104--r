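# Hypothesis DAG structure and algorithms.

build_diamond <- function() {
  dag <- dag_new()
  root <- dag_add_node(dag, "crystal", list(laue = "422"))
  a <- dag_add_node(dag, "data", list(tag = "a"), root)
  b <- dag_add_node(dag, "data", list(tag = "b"), root)
  leaf <- dag_add_node(dag, "anisotropy", list(tag = "leaf"), c(a, b))
  list(dag = dag, root = root, a = a, b = b, leaf = leaf)
}

test_that("node insertion enforces parents, stage order and acyclicity", {
  dag <- dag_new()
  root <- dag_add_node(dag, "crystal", list(laue = "1"))
  expect_length(dag$nodes, 1)
  expect_error(dag_add_node(dag, "data", list(), "no-such-id"), "unknown parent")
  # stage partial order: a twinning node cannot hang off a crystal node
  expect_error(dag_add_node(dag, "twinning", list(), root), "stage order")
  # multiple parents are allowed (merged hypotheses)
  d <- build_diamond()
  expect_equal(sort(d$dag$nodes[[d$leaf]]$parents), sort(c(d$a, d$b)))
  # identical content gives the identical id (idempotent re-run)
  again <- dag_add_node(d$dag, "anisotropy", list(tag = "leaf"), c(d$a, d$b))
  expect_equal(again, d$leaf)
  expect_length(d$dag$nodes, 4)
})

test_that("edges that would close a cycle are rejected atomically", {
  d <- build_diamond()
  before <- d$dag$nodes[[d$root]]$parents
  expect_error(dag_add_edge(d$dag, d$leaf, d$root), "cycle")
  expect_error(dag_add_edge(d$dag, d$root, d$root), "cycle")
  expect_equal(d$dag$nodes[[d$root]]$parents, before)
  expect_error(dag_add_edge(d$dag, d$root, "missing"), "unknown")
})

test_that("topological sort puts every parent before its children", {
  d <- build_diamond()
  ord <- dag_topological_sort(d$dag)
  expect_equal(ord[1], d$root)
  expect_equal(ord[4], d$leaf)
  expect_length(ord, 4)
  # random 20-node DAG: validate every edge against the order
  set.seed(300)
  dag <- dag_new()
  ids <- dag_add_node(dag, "crystal", list(i = 0))
  for (i in 1:19) {
    parents <- sample(ids, size = min(length(ids), sample(1:2, 1)))
    kinds <- c("data", "data", "data")
    ids <- c(ids, dag_add_node(dag, "data", list(i = i),
                               parents[vapply(parents, function(p) dag$nodes[[p]]$kind %in% c("crystal", "data"), logical(1))]))
  }
  ord <- dag_topological_sort(dag)
  expect_length(ord, length(dag$nodes))
  pos <- stats::setNames(seq_along(ord), ord)
  for (id in names(dag$nodes)) {
    for (p in dag$nodes[[id]]$parents) expect_lt(pos[p], pos[id])
  }
})

test_that("shortest path handles trivial, diamond and unreachable cases", {
  d <- build_diamond()
  expect_equal(dag_shortest_path(d$dag, d$leaf, d$leaf), d$leaf)
  expect_null(dag_shortest_path(d$dag, d$a, d$b))
  p <- dag_shortest_path(d$dag, d$root, d$leaf)
  expect_length(p, 3)
  expect_equal(p[1], d$root)
  expect_equal(p[3], d$leaf)
  # lexicographically smaller middle branch wins
  expect_equal(p[2], min(d$a, d$b))
  # brute-force path enumeration oracle: both 2-edge paths exist, none shorter
  expect_true(p[2] %in% c(d$a, d$b))
})

test_that("leaf listing follows rank then id and reacts to new children", {
  dag <- dag_new()
  root <- dag_add_node(dag, "crystal", list(x = 1))
  expect_equal(dag_leaves(dag)[[1]]$id, root)
  a <- dag_add_node(dag, "data", list(tag = "a"), root, rank = 1)
  b <- dag_add_node(dag, "data", list(tag = "b"), root, rank = 2)
  leaves <- dag_leaves(dag)
  expect_equal(vapply(leaves, function(x) x$id, character(1)), c(b, a))
  # adding a child removes the leaf
  dag_add_node(dag, "anisotropy", list(), a)
  expect_false(a %in% vapply(dag_leaves(dag), function(x) x$id, character(1)))
})

test_that("serialize/deserialize round-trips structure and payload scalars", {
  empty <- dag_deserialize(dag_serialize(dag_new()))
  expect_length(empty$nodes, 0)
  dag <- build_triage_dag("422", orders = c(7, 1), twinned = c(TRUE, FALSE),
                          translations = list(c(0, 0, 1 / 7), c(0, 0, 0)))
  txt <- dag_serialize(dag)
  back <- dag_deserialize(txt)
  expect_equal(sort(names(back$nodes)), sort(names(dag$nodes)))
  for (id in names(dag$nodes)) {
    expect_equal(back$nodes[[id]]$parents, dag$nodes[[id]]$parents)
    expect_equal(back$nodes[[id]]$kind, dag$nodes[[id]]$kind)
    expect_equal(back$nodes[[id]]$payload, dag$nodes[[id]]$payload)
  }
  # complex payloads: matrices and TNCS models survive
  dag2 <- dag_new()
  r <- dag_add_node(dag2, "crystal", list(B = diag(c(1, 2, -3)),
                                          model = tncs_model(m = 2, t = c(0.5, 0, 0)),
                                          note = "x"))
  b2 <- dag_deserialize(dag_serialize(dag2))
  expect_equal(b2$nodes[[r]]$payload$B, diag(c(1, 2, -3)))
  expect_equal(b2$nodes[[r]]$payload$model$t, c(0.5, 0, 0))
  expect_error(dag_deserialize("{\"format\": \"something-else\"}"), "not a refltriage")
  expect_error(dag_deserialize("{invalid"), "parse")
})

test_that("DOT export lists every node and edge exactly once", {
  dag <- build_triage_dag("422", orders = c(7, 1), twinned = c(TRUE, FALSE))
  dot <- dag_to_dot(dag)
  lines <- strsplit(dot, "\n")[[1]]
  n_nodes <- sum(grepl("\\[label=", lines))
  n_edges <- sum(grepl("->", lines))
  expect_equal(n_nodes, length(dag$nodes))
  expect_equal(n_edges, sum(vapply(dag$nodes, function(nd) length(nd$parents), numeric(1))))
})

test_that("acyclicity survives random seeded insertion sequences", {
  # property test: 1000 random insertions across many small DAGs
  set.seed(400)
  for (trial in 1:50) {
    dag <- dag_new()
    ids <- dag_add_node(dag, "crystal", list(trial = trial))
    for (i in 1:20) {
      k <- sample(c("data", "data", "anisotropy"), 1)
      ok_parents <- Filter(function(p) dag$nodes[[p]]$kind %in%
                             refltriage:::dag_parent_rules[[k]], ids)
      if (!length(ok_parents)) next
      parents <- sample(ok_parents, min(length(ok_parents), sample(1:2, 1)))
      ids <- c(ids, dag_add_node(dag, k, list(i = i, trial = trial), parents))
    }
    ord <- dag_topological_sort(dag)     # throws if a cycle ever appears
    expect_length(ord, length(dag$nodes))
  }
})
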