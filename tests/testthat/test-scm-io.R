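test_that("read_roster parses classroom-waves and preserves identifiers", {
  p <- write_fixture_roster(withr::local_tempfile(fileext = ".csv"), c(
    "K1,0,A,1", "K1,0,B,1", "K1,0,C,0"
  ))
  rosters <- read_roster(p)
  expect_length(rosters, 1L)
  expect_identical(rosters[[1]]$members, c("A", "B", "C"))
  expect_identical(rosters[[1]]$participants, c("A", "B"))
  expect_identical(rosters[[1]]$classroom_id, "K1")
  expect_identical(rosters[[1]]$wave_id, 0L)
})

test_that("read_roster returns an empty list for a header-only file", {
  p <- write_fixture_roster(withr::local_tempfile(fileext = ".csv"), character())
  expect_identical(read_roster(p), list())
})

test_that("read_roster rejects duplicates and malformed rows with line numbers", {
  p <- write_fixture_roster(withr::local_tempfile(fileext = ".csv"), c(
    "K1,0,A,1", "K1,0,A,1"
  ))
  expect_error(read_roster(p), "duplicate member 'A'.*line 3")
  p2 <- write_fixture_roster(withr::local_tempfile(fileext = ".csv"), c(
    "K1,0,A,1", "K1,x,B,1"
  ))
  expect_error(read_roster(p2), "line 3.*wave_id")
  p3 <- write_fixture_roster(withr::local_tempfile(fileext = ".csv"), c(
    "K1,0,A,2"
  ))
  expect_error(read_roster(p3), "line 2.*participated")
  # same member in different waves is fine
  p4 <- write_fixture_roster(withr::local_tempfile(fileext = ".csv"), c(
    "K1,0,A,1", "K1,1,A,1", "K1,0,B,1", "K1,1,B,0"
  ))
  expect_length(read_roster(p4), 2L)
})

test_that("roster enforces participants within members", {
  expect_error(roster("K1", 0, c("A", "B"), c("A", "Z")), "Z")
  expect_error(roster("K1", 0, c("A", "A"), "A"), "duplicate")
})

test_that("group reports are read, validated, and written back identically", {
  ros <- roster("K1", 0, LETTERS[1:6], LETTERS[1:5])
  reps <- list(
    group_report("A", list(c("A", "B", "C"), c("D", "E")), "F",
                 classroom_id = "K1", wave_id = 0L)
  )
  p <- withr::local_tempfile(fileext = ".json")
  write_group_reports(reps, p)
  back <- read_group_reports(p, ros)
  expect_length(back, 1L)
  expect_length(back[[1]]$groups, 2L)
  expect_identical(back[[1]]$isolates, "F")
  # byte-identical re-serialisation
  p2 <- withr::local_tempfile(fileext = ".json")
  write_group_reports(back, p2)
  expect_identical(readBin(p, "raw", file.size(p)), readBin(p2, "raw", file.size(p2)))
})

test_that("report validation rejects singleton groups, unknown ids, non-participants", {
  ros <- roster("K1", 0, LETTERS[1:6], LETTERS[1:5])
  expect_error(group_report("A", list("D")), "single-member group.*isolate")
  expect_error(group_report("A", list(c("B", "C")), isolates = "B"),
               "both in a group and as an isolate")
  bad <- group_report("A", list(c("B", "Z")), classroom_id = "K1", wave_id = 0L)
  expect_error(validate_report(bad, ros), "A.*unknown member.*Z")
  outsider <- group_report("F", list(c("A", "B")))
  expect_error(validate_report(outsider, ros), "F is not a participant")
})

test_that("expand_report applies clique expansion over participants only", {
  ros <- roster("K1", 0, LETTERS[1:6], LETTERS[1:5])
  net <- expand_report(group_report("A", list(c("A", "B", "C"))), ros)
  expect_identical(network_nodes(net), LETTERS[1:5])
  expect_true(all(has_edge(net, "A", "B"), has_edge(net, "A", "C"),
                  has_edge(net, "B", "C")))
  expect_identical(n_edges(net), 3L)

  # separate groups do not merge
  net2 <- expand_report(group_report("A", list(c("A", "B"), c("B", "C"))), ros)
  expect_true(has_edge(net2, "A", "B") && has_edge(net2, "B", "C"))
  expect_false(has_edge(net2, "A", "C"))

  # pairs with a non-participant endpoint are dropped (F did not participate)
  net3 <- expand_report(group_report("A", list(c("A", "B", "F"))), ros)
  expect_identical(n_edges(net3), 1L)
  expect_true(has_edge(net3, "A", "B"))

  # overlapping groups union at the edge level
  net4 <- expand_report(group_report("A", list(c("A", "B"), c("A", "B", "C"))), ros)
  expect_identical(n_edges(net4), 3L)

  # isolates contribute no edges
  net5 <- expand_report(group_report("A", isolates = c("B", "C")), ros)
  expect_identical(n_edges(net5), 0L)
})

test_that("encode_as_groups emits maximal cliques and degree-zero isolates", {
  nodes <- LETTERS[1:5]
  tri <- affiliative_network(nodes, rbind(c("A", "B"), c("A", "C"), c("B", "C")))
  rep1 <- encode_as_groups(tri, perceiver = "A")
  expect_identical(rep1$groups, list(c("A", "B", "C")))
  expect_identical(rep1$isolates, c("D", "E"))

  path <- affiliative_network(c("A", "B", "C"), rbind(c("A", "B"), c("B", "C")))
  rep2 <- encode_as_groups(path, perceiver = "A")
  expect_identical(rep2$groups, list(c("A", "B"), c("B", "C")))

  empty <- affiliative_network(c("A", "B"))
  rep3 <- encode_as_groups(empty, perceiver = "A")
  expect_identical(rep3$groups, list())
  expect_identical(rep3$isolates, c("A", "B"))
})

test_that("group encoding round-trips random graphs exactly", {
  withr::with_seed(505, {
    for (i in 1:200) {
      g <- rand_graph(sample(2:10, 1))
      ros <- roster("K", 0, network_nodes(g), network_nodes(g))
      back <- expand_report(encode_as_groups(g, perceiver = network_nodes(g)[1]), ros)
      expect_identical(network_edges(back), network_edges(g))
      expect_identical(network_nodes(back), network_nodes(g))
    }
  })
})

test_that("expanded networks never contain self-loops or non-participants", {
  withr::with_seed(99, {
    for (i in 1:50) {
      n <- sample(4:9, 1)
      members <- sprintf("m%02d", 1:n)
      parts <- sort(sample(members, max(2, n - 2)))
      g <- sample(members, 3)
      net <- expand_report(group_report(parts[1], list(g)),
                           roster("K", 0, members, parts))
      e <- network_edges(net)
      expect_true(all(e %in% parts))
      if (nrow(e) > 0) expect_true(all(e[, 1] != e[, 2]))
    }
  })
})

test_that("write_edge_list is canonical and byte-deterministic", {
  net <- affiliative_network(c("A", "B", "C"), rbind(c("B", "A")))
  p <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(net, p)
  expect_identical(readLines(p), c("node_a\tnode_b", "A\tB"))

  empty <- affiliative_network("A")
  p0 <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(empty, p0)
  expect_identical(readLines(p0), "node_a\tnode_b")

  two <- affiliative_network(c("A", "B", "C"), rbind(c("C", "A"), c("B", "A")))
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(two, p2)
  expect_identical(readLines(p2), c("node_a\tnode_b", "A\tB", "A\tC"))

  # equal networks (different construction order) -> identical bytes
  same <- affiliative_network(c("C", "B", "A"), rbind(c("A", "B"), c("A", "C")))
  p3 <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(same, p3)
  expect_identical(readBin(p2, "raw", file.size(p2)),
                   readBin(p3, "raw", file.size(p3)))

  back <- read_edge_list(p2, nodes = c("A", "B", "C"))
  expect_identical(network_edges(back), network_edges(two))
})

test_that("affiliative_network enforces the simple-graph invariants", {
  expect_error(affiliative_network("A", rbind(c("A", "A"))), "self-loop")
  expect_error(affiliative_network(c("A", "B"), rbind(c("A", "Z"))), "Z")
  expect_error(affiliative_network(c("A", "A")), "duplicate")
  # duplicate and reversed pairs collapse to one undirected edge
  net <- affiliative_network(c("A", "B"), rbind(c("A", "B"), c("B", "A")))
  expect_identical(n_edges(net), 1L)
})
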