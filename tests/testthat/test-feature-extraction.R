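test_that("arcsinh transform matches closed form and is strictly monotone", {
  expect_identical(arcsinh_transform(0, 5), 0)
  expect_equal(arcsinh_transform(5, 5), log(1 + sqrt(2)), tolerance = 1e-12)
  expect_equal(arcsinh_transform(5, 5), 0.881374, tolerance = 1e-6)
  set.seed(42)
  x1 <- runif(1000, 0, 1000)
  x2 <- x1 + runif(1000, 1e-6, 10)
  expect_true(all(arcsinh_transform(x1, 5) < arcsinh_transform(x2, 5)))
  expect_error(arcsinh_transform(-1, 5), class = "immunodyn_domain_error")
  expect_error(arcsinh_transform(1, 0), class = "immunodyn_config_error")
  expect_error(arcsinh_transform(1, -2), class = "immunodyn_config_error")
})

test_that("cell frequencies are percentages of labeled cells", {
  panel <- panel_config(cell_types = c("A", "B", "C"),
                        functional_markers = "m1", conditions = "unstim")
  ev <- tiny_event_table(data.frame(
    cell_type = c(rep("A", 50), rep("B", 150)), m1 = 0))
  fq <- compute_frequencies(ev, panel)
  expect_equal(unname(fq["A"]), 25.0)
  expect_equal(unname(fq["B"]), 75.0)
  expect_equal(unname(fq["C"]), 0.0)     # absent subset
  expect_equal(sum(fq), 100)             # disjoint partition conserves mass
  # unassigned cells drop out of the denominator
  ev2 <- tiny_event_table(data.frame(
    cell_type = c(rep("A", 50), rep("unassigned", 50)), m1 = 0))
  expect_equal(unname(compute_frequencies(ev2, panel)["A"]), 100)
  ev3 <- tiny_event_table(data.frame(cell_type = rep("unassigned", 5), m1 = 0))
  expect_error(compute_frequencies(ev3, panel), class = "immunodyn_domain_error")
})

test_that("basal signaling is the mean of transformed intensities", {
  panel <- panel_config(cell_types = c("A", "B"), functional_markers = "m1",
                        conditions = "unstim")
  # transformed values passed through untouched
  ev <- tiny_event_table(data.frame(cell_type = rep("A", 3), m1 = c(1, 2, 3)))
  bs <- compute_basal_signaling(ev, panel)
  expect_equal(unname(bs["basal|A|m1"]), 2.0)
  expect_true(is.na(bs["basal|B|m1"]))   # 0 events -> flagged missing
  # raw zeros transform to 0
  ev0 <- tiny_event_table(data.frame(cell_type = rep("A", 4), m1 = 0),
                          transformed = FALSE)
  expect_equal(unname(compute_basal_signaling(ev0, panel)["basal|A|m1"]), 0)
  # subsets below min_cells are flagged missing
  ev_small <- tiny_event_table(data.frame(cell_type = c("A", "A", "B"),
                                          m1 = c(1, 2, 5)))
  expect_true(is.na(compute_basal_signaling(ev_small, panel)["basal|B|m1"]))
  expect_true(is.na(compute_basal_signaling(ev_small, panel)["basal|A|m1"]))
  panel2 <- panel_config(cell_types = c("A", "B"), functional_markers = "m1",
                         conditions = "unstim", min_cells = 2L)
  expect_equal(unname(compute_basal_signaling(ev_small, panel2)["basal|A|m1"]),
               1.5)
})

test_that("mean of transformed differs from transform of mean (Jensen)", {
  set.seed(7)
  x <- rlnorm(5000, meanlog = 2, sdlog = 1)
  # asinh is concave on the positive axis: E[asinh(X)] < asinh(E[X])
  expect_lt(mean(arcsinh_transform(x, 5)), arcsinh_transform(mean(x), 5))
})

test_that("stimulation responses are arcsinh differences with mask semantics", {
  panel <- panel_config(cell_types = c("A", "B"), functional_markers = c("m1", "m2"),
                        conditions = c("unstim", "stimX"))
  unstim <- tiny_event_table(data.frame(cell_type = rep(c("A", "B"), each = 4),
                                        m1 = 0.5, m2 = 1.0))
  stim <- tiny_event_table(data.frame(cell_type = rep(c("A", "B"), each = 4),
                                      m1 = 2.0, m2 = 1.0),
                           condition = "stimX")
  sr <- compute_stim_response(stim, unstim, panel)
  expect_equal(unname(sr["stim|stimX|A|m1"]), 1.5)
  expect_equal(unname(sr["stim|stimX|A|m2"]), 0)
  # stim table equal to unstim -> all responses zero
  sr0 <- compute_stim_response(
    tiny_event_table(as.data.frame(unstim), condition = "stimX"), unstim, panel)
  expect_true(all(sr0 == 0))
  # masked triple absent from the output
  panel_m <- panel_config(cell_types = c("A", "B"),
                          functional_markers = c("m1", "m2"),
                          conditions = c("unstim", "stimX"),
                          exclusion_mask = data.frame(cell_type = "A",
                                                      marker = "m1",
                                                      condition = "stimX"))
  sr_m <- compute_stim_response(stim, unstim, panel_m)
  expect_false("stim|stimX|A|m1" %in% names(sr_m))
  expect_true("stim|stimX|B|m1" %in% names(sr_m))
  # mismatched sample keys refuse to pair
  stim_bad <- tiny_event_table(as.data.frame(stim), patient = "P9",
                               condition = "stimX")
  expect_error(compute_stim_response(stim_bad, unstim, panel),
               class = "immunodyn_pairing_error")
})

test_that("feature bookkeeping matches the combinatorial counts", {
  # default panel, empty mask: 21 + 21*11 + 21*11 = 483
  expect_equal(nrow(panel_feature_meta(panel_config())), 483)
  # all stim triples excluded: 21 + 231 = 252
  all_mask <- expand.grid(cell_type = default_cell_types(),
                          marker = default_functional_markers(),
                          condition = "LPS+IFNa", stringsAsFactors = FALSE)
  expect_equal(nrow(panel_feature_meta(panel_config(exclusion_mask = all_mask))),
               252)
  meta <- panel_feature_meta(panel_config())
  expect_equal(sum(meta$category == "frequency"), 21)
  expect_equal(sum(meta$category == "basal"), 231)
  expect_false(anyDuplicated(meta$feature) > 0)
})

test_that("extract_features builds a complete matrix and handles edge cases", {
  design <- clean_design(events_per_sample = 400L, seed = 11L)
  sim <- simulate_event_tables(design)
  panel <- panel_config(cell_types = design$cell_types,
                        functional_markers = design$functional_markers,
                        conditions = design$conditions)
  fms <- extract_features(sim$events, panel, sim$sheet)
  meta <- attr(fms$t1, "feature_meta")
  expect_equal(ncol(fms$t1), 4 + 12 + 12)
  expect_true(all(is.finite(unclass(fms$t1))))
  expect_identical(rownames(fms$t1), sim$sheet$patient)

  # permutation invariance: shuffling rows of every event table changes nothing
  set.seed(3)
  shuffled <- lapply(sim$events, function(ev) {
    df <- as.data.frame(ev)[sample(nrow(ev)), , drop = FALSE]
    event_table(df, attr(ev, "patient"), attr(ev, "timepoint"),
                attr(ev, "condition"))
  })
  fms2 <- extract_features(shuffled, panel, sim$sheet)
  expect_equal(unclass(fms$t1), unclass(fms2$t1))
  expect_equal(unclass(fms$t2), unclass(fms2$t2))

  # doubling every cell leaves frequencies and means unchanged
  doubled <- lapply(sim$events, function(ev) {
    df <- as.data.frame(ev)
    event_table(rbind(df, df), attr(ev, "patient"), attr(ev, "timepoint"),
                attr(ev, "condition"))
  })
  fms3 <- extract_features(doubled, panel, sim$sheet)
  expect_equal(unclass(fms$t1), unclass(fms3$t1))

  # a missing unstimulated table is an error naming the sample
  no_unstim <- Filter(function(ev)
    !(attr(ev, "patient") == "P01" && attr(ev, "timepoint") == "T1" &&
        attr(ev, "condition") == "unstim"), sim$events)
  expect_error(extract_features(no_unstim, panel, sim$sheet),
               class = "immunodyn_pairing_error")

  # empty cohort: zero rows, full metadata
  empty_sheet <- sample_sheet(character(0), character(0), numeric(0), numeric(0))
  fme <- extract_features(list(), panel, empty_sheet)
  expect_equal(nrow(fme$t1), 0)
  expect_equal(ncol(fme$t1), 28)
})
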