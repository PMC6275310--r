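test_that("the published worked instance yields precision .57, coverage .40, accuracy .23", {
  ex <- worked_example()
  expect_equal(round(precision(ex$perceived, ex$truth), 2), 0.57)
  expect_equal(round(coverage(ex$perceived, ex$truth), 2), 0.40)
  expect_equal(accuracy_index(ex$perceived, ex$truth), (20 / 35) * (20 / 50))
  expect_equal(round(accuracy_index(ex$perceived, ex$truth), 2), 0.23)
})

test_that("accuracy is 1 iff perceived and true edge sets coincide (nonempty)", {
  nodes <- LETTERS[1:5]
  net <- affiliative_network(nodes, rbind(c("A", "B"), c("C", "D")))
  expect_equal(precision(net, net), 1)
  expect_equal(coverage(net, net), 1)
  expect_equal(accuracy_index(net, net), 1)
  disjoint <- affiliative_network(nodes, rbind(c("A", "C"), c("B", "D")))
  expect_equal(precision(disjoint, net), 0)
  expect_equal(accuracy_index(disjoint, net), 0)
  superset <- affiliative_network(nodes, rbind(c("A", "B"), c("C", "D"), c("A", "E")))
  expect_equal(coverage(superset, net), 1)
  expect_lt(accuracy_index(superset, net), 1)
})

test_that("degenerate inputs follow the documented conventions", {
  nodes <- LETTERS[1:4]
  truth <- affiliative_network(nodes, rbind(c("A", "B")))
  nothing <- affiliative_network(nodes)
  expect_true(is.nan(precision(nothing, truth)))
  expect_equal(coverage(nothing, truth), 0)
  expect_equal(accuracy_index(nothing, truth), 0)
  # empty true network: coverage undefined -> classed error
  expect_error(coverage(truth, nothing), class = "scmnet_undefined_coverage")
  expect_error(accuracy_index(truth, nothing), class = "scmnet_undefined_coverage")
  # node-set mismatch
  other <- affiliative_network(LETTERS[2:5])
  expect_error(precision(truth, other), "same node set")
})

test_that("triangle, two-path and transitivity match hand-computed cases", {
  tri <- affiliative_network(LETTERS[1:3],
                             rbind(c("A", "B"), c("B", "C"), c("A", "C")))
  expect_identical(transitive_triads(tri), 1L)
  expect_identical(two_paths(tri), 0L)
  expect_equal(transitivity_index(tri), 1)

  path <- affiliative_network(LETTERS[1:3], rbind(c("A", "B"), c("B", "C")))
  expect_identical(transitive_triads(path), 0L)
  expect_identical(two_paths(path), 1L)
  expect_equal(transitivity_index(path), 0)

  k4e <- affiliative_network(LETTERS[1:4],
                             rbind(c("A", "B"), c("A", "C"), c("A", "D"),
                                   c("B", "C"), c("B", "D")))
  expect_identical(transitive_triads(k4e), 2L)
  expect_identical(two_paths(k4e), 2L)
  expect_equal(transitivity_index(k4e), 0.75)

  star <- affiliative_network(LETTERS[1:4],
                              rbind(c("A", "B"), c("A", "C"), c("A", "D")))
  expect_equal(transitivity_index(star), 0)

  # no connected triples: missing, not zero
  expect_true(is.na(transitivity_index(affiliative_network(LETTERS[1:3]))))
  lone <- affiliative_network(LETTERS[1:4], rbind(c("A", "B")))
  expect_true(is.na(transitivity_index(lone)))
})

test_that("triad counts agree with brute-force enumeration and igraph", {
  withr::with_seed(301, {
    for (i in 1:300) {
      g <- rand_graph(sample(3:6, 1))
      o <- oracle_triples(g)
      expect_identical(transitive_triads(g), as.integer(o$closed))
      expect_identical(two_paths(g), as.integer(o$open))
      expect_equal(transitivity_index(g), oracle_transitivity(g))
      ig_t <- suppressWarnings(
        igraph::transitivity(scmnet:::as_igraph(g), type = "global"))
      mine <- transitivity_index(g)
      if (is.na(mine)) expect_true(is.na(ig_t) || is.nan(ig_t))
      else expect_equal(mine, ig_t)
    }
  })
})

test_that("accuracy agrees with the brute-force set oracle on random pairs", {
  withr::with_seed(302, {
    for (i in 1:200) {
      n <- sample(3:6, 1)
      perc <- rand_graph(n)
      truth <- rand_graph(n)
      if (n_edges(truth) == 0) {
        expect_error(accuracy_index(perc, truth), class = "scmnet_undefined_coverage")
      } else {
        expect_equal(accuracy_index(perc, truth), oracle_accuracy(perc, truth))
      }
    }
  })
})

test_that("accuracy respects its bounds and is dominated by its components", {
  withr::with_seed(303, {
    for (i in 1:100) {
      n <- sample(4:7, 1)
      perc <- rand_graph(n)
      truth <- rand_graph(n)
      if (n_edges(truth) == 0) next
      acc <- accuracy_index(perc, truth)
      cov <- coverage(perc, truth)
      expect_gte(acc, 0)
      expect_lte(acc, 1)
      expect_gte(cov, 0)
      expect_lte(cov, 1)
      if (n_edges(perc) > 0) {
        prec <- precision(perc, truth)
        expect_lte(acc, min(prec, cov) + 1e-12)
      }
      ti <- transitivity_index(truth)
      if (!is.na(ti)) {
        expect_gte(ti, 0)
        expect_lte(ti, 1)
      }
    }
  })
})

test_that("adding a correct tie or dropping a false one never hurts", {
  withr::with_seed(304, {
    for (i in 1:50) {
      n <- 6
      perc <- rand_graph(n, 0.4)
      truth <- rand_graph(n, 0.5)
      if (n_edges(truth) == 0) next
      pk <- edge_keys(perc)
      tk <- edge_keys(truth)
      # add a true-but-undepicted edge: coverage must not decrease
      addable <- setdiff(tk, pk)
      if (length(addable) > 0) {
        e2 <- rbind(network_edges(perc),
                    scmnet:::keys_to_matrix(addable[1]))
        perc2 <- affiliative_network(network_nodes(perc), e2)
        expect_gte(coverage(perc2, truth), coverage(perc, truth))
      }
      # remove a depicted non-true edge: precision must not decrease
      false_keys <- setdiff(pk, tk)
      if (length(false_keys) > 0 && length(pk) > 1) {
        keep <- setdiff(pk, false_keys[1])
        perc3 <- affiliative_network(network_nodes(perc),
                                     scmnet:::keys_to_matrix(keep))
        expect_gte(precision(perc3, truth), precision(perc, truth))
      }
    }
  })
})

test_that("accuracy_table scores every perceiver and flags degenerate cases", {
  parts <- c("A", "B", "C")
  ab <- rbind(c("A", "B"))
  perceived <- list(
    A = affiliative_network(parts, ab),
    B = affiliative_network(parts, rbind(c("A", "B"), c("A", "C"))),
    C = affiliative_network(parts)
  )
  cw <- classroom_wave(roster("K", 0, parts, parts), perceived)
  tab <- accuracy_table(cw)
  expect_identical(nrow(tab), 3L)
  expect_equal(tab$accuracy[tab$perceiver == "A"], 1)
  expect_equal(tab$precision[tab$perceiver == "B"], 0.5)
  expect_true(tab$zero_depicted[tab$perceiver == "C"])
  expect_equal(tab$accuracy[tab$perceiver == "C"], 0)

  # empty true network -> warning, zero-row table
  lonely <- lapply(parts, function(p) affiliative_network(parts))
  names(lonely) <- parts
  cw0 <- classroom_wave(roster("K", 0, parts, parts), lonely)
  expect_warning(tab0 <- accuracy_table(cw0), "empty true network")
  expect_identical(nrow(tab0), 0L)
  expect_true(attr(tab0, "excluded"))
})
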