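test_that("the default design is 36 trials over 198 s in 16.5-s blocks", {
  des <- build_dms_design(seed = 1)
  expect_equal(nrow(des$trials), 36)
  expect_equal(des$duration, 198)
  expect_equal(des$block_len, 3 * (1.0 + 1.5 + 1.0 + 2.0))
  expect_equal(des$block_len, 16.5)
  expect_equal(unique(table(des$trials$block)), 3L)
  # alternating conditions, DMS first
  ons <- block_onsets(des)
  expect_equal(ons$condition, rep(c("DMS", "CTL"), 6))
  expect_equal(ons$onset, seq(0, by = 16.5, length.out = 12))
  # attention evenly spaced over the DMS blocks, constant low for CTL
  att <- unique(des$trials[des$trials$condition == "DMS",
                           c("block", "attention")])$attention
  expect_equal(att, seq(0.24, 0.34, length.out = 6))
  expect_equal(unique(des$trials$attention[des$trials$condition == "CTL"]),
               0.05)
  # match pattern per block and CTL degradation
  expect_equal(des$trials$match, rep(c(TRUE, FALSE, TRUE), 12))
  expect_true(all(des$trials$degraded[des$trials$condition == "CTL"]))
  expect_false(any(des$trials$degraded[des$trials$condition == "DMS"]))
})

test_that("an empty design has zero trials and duration", {
  des <- build_dms_design(n_blocks = 0)
  expect_equal(nrow(des$trials), 0)
  expect_equal(des$duration, 0)
  expect_equal(nrow(design_segments(des)), 0)
})

test_that("design segments tile each trial and reset attention in the ITI", {
  des <- build_dms_design(n_blocks = 2, seed = 5)
  seg <- design_segments(des)
  expect_equal(nrow(seg), 4 * nrow(des$trials))
  expect_equal(sum(seg$t1 - seg$t0), des$duration)
  expect_true(all(seg$attention[seg$phase == "iti"] == des$ctl_attention))
  s1 <- seg[seg$phase == "s1", ]
  expect_equal(s1$t1 - s1$t0, rep(1.0, nrow(s1)))
  expect_equal(seg$t1[seg$phase == "delay"] - seg$t0[seg$phase == "delay"],
               rep(1.5, sum(seg$phase == "delay")))
})

test_that("designs are reproducible and mismatch probes are discriminable", {
  d1 <- build_dms_design(seed = 77)
  d2 <- build_dms_design(seed = 77)
  expect_identical(d1$trials, d2$trials)
  ovl <- shape_overlap_matrix()
  mm <- d1$trials[!d1$trials$match, ]
  expect_true(all(mm$s1 != mm$s2))
  expect_true(all(ovl[cbind(mm$s1, mm$s2)] <= 1))
})

test_that("stimulus patterns activate stroke cells on the right channels", {
  p <- make_stimulus("cross")
  expect_s3_class(p, "stimulus_pattern")
  expect_true(all(p$grid %in% c(0, 1)))
  expect_equal(p$grid, pmax(p$h, p$v))
  expect_equal(sum(p$h[7, 5:9]), 5)            # horizontal bar
  expect_equal(sum(p$v[5:9, 7]), 5)            # vertical bar
  expect_equal(sum(p$h > 0 & p$v > 0), 1)      # one intersection cell
  blank <- make_stimulus("blank")
  expect_equal(sum(blank$grid), 0)
  expect_error(make_stimulus("nonesuch"), "unknown shape_id")
})

test_that("degradation retains active cells binomially", {
  full <- make_stimulus("square")
  n_full <- sum(full$grid > 0)
  set.seed(11)
  kept <- replicate(400, sum(make_stimulus("square", degraded = TRUE,
                                           retention = 0.5)$grid > 0))
  expect_equal(mean(kept), n_full * 0.5, tolerance = 0.05)
  expect_gt(var(kept), 0)
  expect_true(all(kept <= n_full))
  # degraded cells are a subset of the intact shape
  set.seed(12)
  d <- make_stimulus("square", degraded = TRUE, retention = 0.5)
  expect_true(all(full$grid[d$grid > 0] == 1))
})

test_that("the shape library offers at least 8 distinct discriminable shapes", {
  ids <- setdiff(names(shape_library()), "blank")
  expect_gte(length(ids), 8)
  grids <- lapply(ids, function(s) make_stimulus(s)$grid)
  for (a in seq_along(grids))
    for (b in seq_len(a - 1))
      expect_false(identical(grids[[a]], grids[[b]]))
  # every shape has at least one low-overlap mismatch partner
  ovl <- shape_overlap_matrix()
  for (s in ids)
    expect_gte(sum(ovl[s, setdiff(ids, s)] <= 1), 1)
})
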