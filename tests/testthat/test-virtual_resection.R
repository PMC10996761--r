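test_that("candidates order by ascending LE, then the rate fallback", {
  ## three hot contacts (rate > 1/min) with distinct LE, two cool ones
  ids <- c("H1", "H2", "H3", "C1", "C2")
  contacts <- make_contacts(ids, cbind(seq(10, 50, by = 10), 0, 0))
  dur <- 10
  events <- rbind(
    make_events("H1", seq(0.5, 599, by = 15)),   # 4/min
    make_events("H2", seq(0.7, 599, by = 20)),   # 3/min
    make_events("H3", seq(0.9, 599, by = 30)),   # 2/min
    make_events("C1", seq(1.1, 599, by = 80)),   # 0.75/min
    make_events("C2", seq(1.3, 599, by = 120)))  # 0.5/min
  p <- fr_patient("cand", contacts, events, dur)
  g <- build_mi_graph(p)
  ord <- candidate_order(p, g)
  le <- sapply(ids[1:3], function(id) local_efficiency(g, id))
  expect_setequal(ord[1:3], c("H1", "H2", "H3"))
  expect_equal(ord[1:3], ids[1:3][order(le, -c(4, 3, 2), ids[1:3])])
  ## fallback: cool contacts by descending rate
  expect_equal(ord[4:5], c("C1", "C2"))
  ## no contact above 1/min: everything ordered by rate
  q <- p
  q$events <- q$events[q$events$contact_id %in% c("C1", "C2"), ]
  expect_equal(candidate_order(q, build_mi_graph(q)), c("C1", "C2"))
  ## no FR at all is an error
  r <- p
  r$events <- make_events("H1", 5, "RonO", 120)
  expect_error(candidate_order(r, g), "poor sampling")
})

test_that("sphere membership is a closed ipsilateral ball", {
  ids <- c("A", "B", "C", "D")
  contacts <- make_contacts(ids, rbind(c(10, 0, 0), c(20, 0, 0),
                                       c(-12, 0, 0), c(40, 0, 0)),
                            hemisphere = c("R", "R", "L", "R"))
  ## B exactly at the 10 mm boundary: included
  expect_setequal(sphere_members(contacts, c(10, 0, 0), 10, "R"), c("A", "B"))
  ## contralateral contact 2 mm outside its hemisphere: excluded even
  ## when inside the ball
  expect_false("C" %in% sphere_members(contacts, c(-10, 0, 0), 25, "R"))
  ## only the centre contact inside
  expect_equal(sphere_members(contacts, c(40, 0, 0), 5, "R"), "D")
})

test_that("the radius grows as candidate distance plus the 1 cm buffer", {
  ids <- c("A", "B", "C", "D")
  ## distances from A: 25, 38, 55 mm; same lobe so no three-lobe stop
  contacts <- make_contacts(ids, rbind(c(0, 0, 0), c(25, 0, 0),
                                       c(38, 0, 0), c(55, 0, 0)))
  dur <- 10
  ## all rates below 1/min: the candidate order is the deterministic
  ## descending-rate fallback A > B > C > D
  events <- rbind(
    make_events("A", seq(10, 580, length.out = 9)),  # 0.9/min
    make_events("B", seq(20, 570, length.out = 7)),  # 0.7/min
    make_events("C", seq(30, 560, length.out = 5)),  # 0.5/min
    make_events("D", seq(40, 550, length.out = 3)))  # 0.3/min
  p <- fr_patient("radius", contacts, events, dur)
  expect_equal(candidate_order(p, build_mi_graph(p)), c("A", "B", "C", "D"))
  tr <- run_virtual_resection(p, stub_svm(always = FALSE))
  expect_equal(tr$status, "candidates_exhausted")
  ## iteration 1: 10 mm (A only); then 25+10, 38+10, 55+10
  expect_equal(tr$trace$radius_mm, c(10, 35, 48, 65))
  expect_equal(tr$trace$n_resected, 1:4)
  ## nestedness and monotone FR RR
  sets <- tr$trace$resected_set
  for (k in seq_len(length(sets) - 1))
    expect_true(all(sets[[k]] %in% sets[[k + 1]]))
  expect_true(all(diff(tr$trace$fr_rr) >= 0))
  ## an always-positive model stops at iteration 1
  tr2 <- run_virtual_resection(p, stub_svm(always = TRUE))
  expect_equal(tr2$status, "seizure_free")
  expect_equal(nrow(tr2$trace), 1L)
  ## determinism
  tr3 <- run_virtual_resection(p, stub_svm(always = FALSE))
  expect_identical(as.data.frame(tr3), as.data.frame(tr))
})

test_that("spanning three lobes stops the simulation as non-seizure-free", {
  ids <- c("F", "P", "O")
  contacts <- make_contacts(ids, rbind(c(10, 40, 10), c(10, 0, 50),
                                       c(10, -80, 0)),
                            lobe = c("frontal", "parietal", "occipital"))
  events <- rbind(
    make_events("F", seq(10, 580, length.out = 9)),
    make_events("P", seq(20, 570, length.out = 7)),
    make_events("O", seq(30, 560, length.out = 5)))
  p <- fr_patient("lobes", contacts, events, 10)
  tr <- run_virtual_resection(p, stub_svm(always = FALSE))
  expect_equal(tr$status, "three_lobe_stop")
  last <- tr$trace[nrow(tr$trace), ]
  expect_gte(last$n_lobes, 3)
  expect_true(is.na(last$svm_label))
  expect_false(tr$virtual_seizure_free)
})

test_that("overlap contingency reproduces the closed-form metrics", {
  uni <- sprintf("c%02d", 1:20)
  ## identical sets: everything 1, nothing novel
  ct <- overlap_contingency(uni[1:6], uni[1:6], uni)
  for (m in c("sensitivity", "specificity", "ppv", "npv", "accuracy", "f1"))
    expect_equal(as.numeric(ct[[m]]), 1)
  expect_equal(as.numeric(ct$novel_r), 0)
  ## superset: percent_r 1, novel_r positive
  ct2 <- overlap_contingency(uni[1:10], uni[1:6], uni)
  expect_equal(as.numeric(ct2$percent_r), 1)
  expect_equal(as.numeric(ct2$novel_r), 0.4)
  ## ppv 0.5 with sensitivity 1 gives F1 = 2/3
  ct3 <- overlap_contingency(uni[1:8], uni[1:4], uni)
  expect_equal(as.numeric(ct3$ppv), 0.5)
  expect_equal(as.numeric(ct3$sensitivity), 1)
  expect_equal(as.numeric(ct3$f1), 2 / 3)
  ## percent_r is sensitivity on random instances; counts partition
  set.seed(19)
  for (rep in 1:20) {
    v <- sample(uni, sample(0:20, 1))
    a <- sample(uni, sample(1:20, 1))
    ct <- overlap_contingency(v, a, uni)
    expect_identical(as.numeric(ct$percent_r), as.numeric(ct$sensitivity))
    expect_equal(ct$tp + ct$fp + ct$tn + ct$fn, 20L)
    expect_equal(ct$tp / (ct$tp + ct$fn), as.numeric(ct$sensitivity))
  }
  ## empty actual set flags sensitivity
  expect_true(is.na(overlap_contingency(uni[1:3], character(0), uni)$sensitivity))
})
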