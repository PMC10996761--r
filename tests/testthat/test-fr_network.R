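test_that("the MI graph has the documented structure and flags", {
  p <- tiny_patient()
  g <- build_mi_graph(p)
  expect_setequal(g$nodes, c("A1", "A2", "A3"))  # A4 generates only RonS
  expect_equal(g$adjacency, t(g$adjacency))
  expect_true(all(diag(g$adjacency) == 0))
  pos <- g$adjacency > 0
  expect_equal(g$lengths[pos], 1 / g$adjacency[pos])
  expect_true(all(is.infinite(g$lengths[!pos & upper.tri(pos)])))
  ## fRonS rate never above 1/min here -> poor sampling flag
  expect_true(g$poor_sampling)
  ## a single FR-generating contact -> degenerate graph
  q <- p
  q$events <- q$events[q$events$contact_id %in% c("A1", "A4"), ]
  expect_true(build_mi_graph(q)$degenerate)
})

test_that("local efficiency matches the hand anchors", {
  ## complete graph with equal weights: normalization forces unit
  ## weights, so every node's LE is 1
  adj <- matrix(0.4, 4, 4); diag(adj) <- 0
  g <- graph_from_adjacency(adj)
  for (i in 1:4) expect_equal(local_efficiency(g, i), 1)
  ## isolated node
  adj2 <- matrix(0, 3, 3); adj2[1, 2] <- adj2[2, 1] <- 1
  g2 <- graph_from_adjacency(adj2)
  expect_equal(local_efficiency(g2, 3), 0)
  expect_equal(local_efficiency(g2, 1), 0)  # single neighbour
})

test_that("graph metrics equal brute-force oracles on random graphs", {
  set.seed(77)
  for (rep in 1:40) {
    n <- sample(3:8, 1)
    adj <- random_adjacency(n, density = runif(1, 0.3, 0.9))
    g <- graph_from_adjacency(adj)
    for (i in seq_len(n))
      expect_lt(abs(local_efficiency(g, i) - oracle_le(adj, i)), 1e-10)
    cpl <- characteristic_path_length(g)
    o_cpl <- oracle_cpl(adj)
    if (is.na(o_cpl)) expect_true(is.na(cpl))
    else expect_lt(abs(as.numeric(cpl) - o_cpl), 1e-10)
    ge <- global_efficiency(g)
    expect_lt(abs(as.numeric(ge) - oracle_ge(adj)), 1e-10)
    ## radius on random spatial configurations
    coords <- matrix(runif(n * 3, -50, 50), n)
    rates <- runif(n, 0.1, 5)
    w <- outer(rates, rates, function(a, b) (a + b) / 2) * as.matrix(dist(coords))
    expect_lt(abs(graph_radius(coords, rates, "rate_distance") -
                  oracle_radius(w)), 1e-10)
    expect_lt(abs(graph_radius(coords, weight_rule = "distance_only") -
                  oracle_radius(as.matrix(dist(coords)))), 1e-10)
  }
})

test_that("characteristic path length matches the hand examples", {
  ## 2 nodes, MI 0.5 -> single length 2
  adj <- matrix(c(0, .5, .5, 0), 2)
  expect_equal(as.numeric(characteristic_path_length(graph_from_adjacency(adj))), 2)
  ## 3-node line with lengths 1,1 and one missing edge: shortest paths
  ## 1, 1 and 2 via the middle -> mean 4/3
  adj3 <- matrix(0, 3, 3)
  adj3[1, 2] <- adj3[2, 1] <- 1
  adj3[2, 3] <- adj3[3, 2] <- 1
  expect_equal(as.numeric(characteristic_path_length(graph_from_adjacency(adj3))),
               4 / 3)
  ## subsets below two nodes are flagged
  g <- graph_from_adjacency(adj3)
  expect_true(is.na(characteristic_path_length(g, g$nodes[1])))
})

test_that("graph radius has the declared conventions", {
  expect_equal(graph_radius(rbind(c(0, 0, 0), c(20, 0, 0)),
                            weight_rule = "distance_only"), 20)
  expect_equal(graph_radius(rbind(c(5, 5, 5)), weight_rule = "distance_only"), 0)
  expect_true(is.na(graph_radius(matrix(numeric(0), 0, 3),
                                 weight_rule = "distance_only")))
})

test_that("global efficiency uses reciprocal direct lengths", {
  adj <- matrix(c(0, .5, .5, 0), 2)
  expect_equal(as.numeric(global_efficiency(graph_from_adjacency(adj))), 0.5)
  disc <- matrix(0, 2, 2)
  expect_equal(as.numeric(global_efficiency(graph_from_adjacency(disc))), 0)
  g <- graph_from_adjacency(adj)
  expect_true(is.na(global_efficiency(g, g$nodes[1])))
})

test_that("spatial FRnet hits its anchors and composes from radii", {
  p <- tiny_patient()
  rates <- contact_rates(p)
  ## resecting every FR-generating node zeroes the metric
  expect_equal(spatial_frnet(p, c("A1", "A2", "A3"), rates), 0)
  expect_equal(spatial_frnet(p, p$contacts$contact_id, rates), 0)
  ## a single resected FR node: resected-only radius is 0
  fr_nodes <- c("A1", "A2", "A3")
  r <- setNames(rates$fr350[match(fr_nodes, rates$contact_id)], fr_nodes)
  whole <- graph_radius(frnetsim:::contact_coords(p$contacts, fr_nodes), r)
  expect_equal(spatial_frnet(p, "A1", rates), sqrt(whole))
  ## composition on random patients
  set.seed(3)
  for (rep in 1:10) {
    n <- 8
    ids <- sprintf("C%d", 1:n)
    contacts <- make_contacts(ids, matrix(runif(n * 3, 0, 80), n))
    events <- do.call(rbind, lapply(seq_len(n), function(i)
      make_events(ids[i], sort(runif(rpois(1, 30) + 1, 0, 600)))))
    pp <- fr_patient("r", contacts, events, 10)
    rr <- contact_rates(pp)
    res <- sample(ids, 4)
    rv <- setNames(rr$fr350, rr$contact_id)
    w_all <- oracle_radius(outer(rv, rv, function(a, b) (a + b) / 2) *
                             as.matrix(dist(frnetsim:::contact_coords(contacts))))
    w_res <- oracle_radius(outer(rv[res], rv[res], function(a, b) (a + b) / 2) *
                             as.matrix(dist(frnetsim:::contact_coords(contacts, res))))
    expect_lt(abs(spatial_frnet(pp, res, rr) - sqrt(max(0, w_all - w_res))), 1e-10)
  }
})

test_that("temporal FRnet-A is the resected/whole path-length ratio", {
  set.seed(8)
  ## full resection -> exactly 1
  adj <- random_adjacency(6, 0.8)
  g <- graph_from_adjacency(adj)
  expect_equal(temporal_frnet_a(g, g$nodes), 1)
  ## resecting the pair with the single largest length exceeds 1
  adj3 <- matrix(0, 3, 3)
  adj3[1, 2] <- adj3[2, 1] <- 1     # length 1
  adj3[2, 3] <- adj3[3, 2] <- 0.2   # length 5
  adj3[1, 3] <- adj3[3, 1] <- 0.5   # length 2
  g3 <- graph_from_adjacency(adj3)
  expect_gt(temporal_frnet_a(g3, g3$nodes[c(2, 3)]), 1)
  ## oracle ratio on random graphs
  for (rep in 1:15) {
    adj <- random_adjacency(7, 0.7)
    g <- graph_from_adjacency(adj)
    sub <- sample(7, 3)
    o_num <- oracle_cpl(adj[sub, sub, drop = FALSE])
    o_den <- oracle_cpl(adj)
    got <- temporal_frnet_a(g, g$nodes[sub])
    if (is.na(o_num) || is.na(o_den)) expect_true(is.na(got))
    else expect_lt(abs(got - o_num / o_den), 1e-10)
  }
  ## single-node resection is flagged as unavailable
  expect_true(is.na(temporal_frnet_a(g3, g3$nodes[1])))
})

test_that("temporal FRnet-B averages positive LE over the unresected set", {
  set.seed(12)
  adj <- random_adjacency(7, 0.8)
  g <- graph_from_adjacency(adj)
  ## everything resected -> degenerate convention 1.0
  all_res <- temporal_frnet_b(g, g$nodes)
  expect_equal(as.numeric(all_res), 1)
  expect_equal(metric_flag(all_res), "degenerate")
  ## unresected isolated nodes -> degenerate as well
  iso <- matrix(0, 4, 4); iso[1, 2] <- iso[2, 1] <- 1
  gi <- graph_from_adjacency(iso)
  expect_equal(as.numeric(temporal_frnet_b(gi, gi$nodes[1:2])), 1)
  ## matches the mean of the LE oracle over qualifying nodes
  for (rep in 1:10) {
    adj <- random_adjacency(6, 0.7)
    g <- graph_from_adjacency(adj)
    res <- sample(g$nodes, 2)
    keep <- setdiff(seq_len(6), match(res, g$nodes))
    les <- vapply(keep, function(i) oracle_le(adj, i), numeric(1))
    les <- les[les > 0]
    got <- temporal_frnet_b(g, res)
    if (length(les) == 0) expect_equal(as.numeric(got), 1)
    else expect_lt(abs(as.numeric(got) - mean(les)), 1e-10)
  }
  ## with frnetB_scope = "all" resected nodes are evaluated too
  o_all <- fr_options(frnetB_scope = "all")
  adj <- random_adjacency(6, 0.9)
  g <- graph_from_adjacency(adj)
  les <- vapply(1:6, function(i) oracle_le(adj, i), numeric(1))
  les <- les[les > 0]
  expect_lt(abs(as.numeric(temporal_frnet_b(g, g$nodes[1:3], o_all)) -
                mean(les)), 1e-10)
})

test_that("feature vectors hit the full- and empty-resection anchors", {
  p <- tiny_patient()
  full <- feature_vector(p, p$contacts$contact_id)
  expect_equal(as.numeric(full$fr_rr), 1)
  expect_equal(as.numeric(full$spatial_frnet), 0)
  expect_equal(as.numeric(full$temporal_frnet_a), 1)
  expect_equal(as.numeric(full$temporal_frnet_b), 1)
  empty <- feature_vector(p, character(0))
  expect_equal(as.numeric(empty$fr_rr), 0)
  expect_true(is.na(empty$temporal_frnet_a))
})

test_that("growing the resected set never decreases the FR RR", {
  p <- tiny_patient()
  sets <- list("A1", c("A1", "A2"), c("A1", "A2", "A3"),
               c("A1", "A2", "A3", "A4"))
  rrs <- vapply(sets, function(s)
    as.numeric(event_resection_ratio(p, "fr350", s)), numeric(1))
  expect_true(all(diff(rrs) >= 0))
})

test_that("graph export writes readable edge lists", {
  p <- tiny_patient()
  g <- build_mi_graph(p)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_mi_graph(g, csv)
  edges <- utils::read.csv(csv)
  expect_named(edges, c("node_a", "node_b", "mi_bits", "length"))
  gml <- withr::local_tempfile(fileext = ".graphml")
  write_mi_graph(g, gml, format = "graphml")
  expect_true(file.size(gml) > 0)
})
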