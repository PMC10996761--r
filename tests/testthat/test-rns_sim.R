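test_that("the stimulation field is a strict 15 mm ball around any lead contact", {
  ids <- c("A", "B", "C")
  contacts <- make_contacts(ids, rbind(c(15, 0, 0), c(5, 0, 0), c(100, 0, 0)))
  leads <- list(stim_coords = matrix(rep(c(0, 0, 0), 8), 8, 3, byrow = TRUE))
  ## exactly 15.0 mm: excluded (strict inequality); 5 mm: included
  expect_setequal(stimulated_set(contacts, leads), "B")
  expect_setequal(stimulated_set(contacts, leads, field_radius_mm = 15.01),
                  c("A", "B"))
  ## monotone in the field radius
  set.seed(23)
  rc <- make_contacts(sprintf("r%d", 1:30), matrix(runif(90, 0, 80), 30))
  lead2 <- list(stim_coords = matrix(runif(24, 0, 80), 8, 3))
  prev <- character(0)
  for (r in c(5, 10, 20, 40)) {
    cur <- stimulated_set(rc, lead2, r)
    expect_true(all(prev %in% cur))
    prev <- cur
  }
  ## far leads stimulate nothing and the metrics flag it
  far <- list(stim_coords = matrix(500, 8, 3))
  expect_length(stimulated_set(contacts, far), 0)
})

test_that("stimulation metrics mirror the resection-ratio definitions", {
  p <- tiny_patient()      # SOZ = A1, A2
  g <- build_mi_graph(p)
  m <- rns_metrics(p, c("A1", "A2"), g)
  expect_equal(as.numeric(m$soz_sr), 1)
  expect_equal(as.numeric(m$fr_sr),
               as.numeric(event_resection_ratio(p, "fr350", c("A1", "A2"))))
  empty <- rns_metrics(p, character(0), g)
  expect_true(is.na(empty$rns_temporal_frnet))
})

test_that("stimulating the coupled halo scores higher SGe than the autonomous core", {
  set.seed(31)
  diffs <- replicate(12, {
    el <- generate_patient(synth_config(), seed = sample.int(2^30, 1))
    g <- build_mi_graph(el$patient)
    halo <- rns_metrics(el$patient, el$truth$halo, g)$rns_temporal_frnet
    core <- rns_metrics(el$patient, el$truth$core, g)$rns_temporal_frnet
    as.numeric(halo) - as.numeric(core)
  })
  expect_gt(mean(diffs, na.rm = TRUE), 0)
})

test_that("virtual leads are contiguous 4-contact windows at the top FR sites", {
  ## two parallel shafts of 6 contacts, 5 mm apart; top rate mid-shaft
  mk <- function(shaft, y) make_contacts(sprintf("%sC%d", shaft, 1:6),
                                         cbind(seq(5, 30, by = 5), y, 0),
                                         shaft = shaft)
  contacts <- rbind(mk("S1", 0), mk("S2", 30))
  dur <- 10
  events <- rbind(
    make_events("S1C3", seq(0.1, 599, by = 10)),  # global top, mid-shaft
    make_events("S1C5", seq(0.2, 599, by = 60)),
    make_events("S2C1", seq(0.3, 599, by = 20)),  # top of second shaft, at its end
    make_events("S2C4", seq(0.4, 599, by = 80)))
  p <- fr_patient("leads", contacts, events, dur)
  leads <- virtual_placement(p)
  ids <- attr(leads, "contact_ids")
  ## lead 1 spans positions i-1 .. i+2 around S1C3
  expect_equal(ids[1:4], c("S1C2", "S1C3", "S1C4", "S1C5"))
  ## lead 2 clips at the shaft end around S2C1
  expect_equal(ids[5:8], c("S2C1", "S2C2", "S2C3", "S2C4"))

  ## bilateral placement puts one lead per hemisphere
  contacts_bi <- rbind(mk("S1", 0), mk("S2", 30))
  contacts_bi$hemisphere[contacts_bi$shaft_id == "S2"] <- "L"
  contacts_bi$x_mm[contacts_bi$shaft_id == "S2"] <-
    -contacts_bi$x_mm[contacts_bi$shaft_id == "S2"]
  pb <- fr_patient("bi", contacts_bi, events, dur)
  lb <- virtual_placement(pb, bilateral = TRUE)
  idb <- attr(lb, "contact_ids")
  hemi <- contacts_bi$hemisphere[match(idb, contacts_bi$contact_id)]
  expect_setequal(unique(hemi[1:4]), "R")
  expect_setequal(unique(hemi[5:8]), "L")
  expect_true(lb$bilateral)

  ## a single-shaft implant cannot host a second lead
  ps <- fr_patient("solo", mk("S1", 0),
                   make_events("S1C3", seq(0.1, 599, by = 10)), dur)
  expect_error(virtual_placement(ps), "second shaft")

  ## short shaft: all its contacts used, padded from the nearest shaft
  short <- rbind(make_contacts(sprintf("S1C%d", 1:2), cbind(c(5, 10), 0, 0),
                               shaft = "S1"),
                 mk("S2", 10))
  psh <- fr_patient("short", short,
                    rbind(make_events("S1C1", seq(0.1, 599, by = 10)),
                          make_events("S2C2", seq(0.2, 599, by = 30))), dur)
  lsh <- virtual_placement(psh)
  expect_equal(sum(startsWith(attr(lsh, "contact_ids")[1:4], "S1")), 2)
})

test_that("virtual placement recovers at least the FR capture of distant actual leads", {
  ## actual leads planted far from the core: the virtual placement at
  ## the highest-rate sites must capture at least as many FR events
  set.seed(41)
  ok <- replicate(20, {
    el <- generate_patient(synth_config(), seed = sample.int(2^30, 1))
    p <- el$patient
    far <- matrix(rep(c(0, -200, 200), 8), 8, 3, byrow = TRUE)
    actual <- rns_metrics(p, stimulated_set(p$contacts, list(stim_coords = far)))
    virt <- rns_metrics(p, stimulated_set(p$contacts, virtual_placement(p)))
    vfr <- as.numeric(virt$fr_sr)
    afr <- as.numeric(actual$fr_sr)
    if (is.na(afr)) afr <- 0
    vfr >= afr
  })
  expect_gte(mean(ok), 0.9)
})
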