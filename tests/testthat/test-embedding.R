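one_module_spec <- function(x = 0, y = 0, z = 0, name = "IT") {
  data.frame(name = name, x = x, y = y, z = z, region = name,
             receives_connectome_input = TRUE, sends_feedback = TRUE,
             stringsAsFactors = FALSE)
}

test_that("star-graph embedding wires afferents with mean coupling G/81", {
  con <- star_connectome(leaves = 4, weight = 0.2)
  hy <- build_embedding(con, one_module_spec(0, 0, 0), G = 0.15, seed = 9)
  p <- hy$placements$IT
  expect_equal(p$host, 1)
  expect_setequal(p$afferents, 2:5)
  expect_equal(dim(p$coupling_samples), c(4, 81))
  expect_lt(abs(mean(p$coupling_samples) - 0.15 / 81) / (0.15 / 81), 0.05)
  expect_true(all(p$coupling_samples >= 0))
  expect_equal(p$structural_weights, rep(0.2, 4))
})

test_that("coupling-sample mean converges to G/81 over 1e4 draws", {
  n <- 125
  w <- matrix(0.3, n, n); diag(w) <- 0
  con <- connectome(w, matrix(seq_len(3 * n), n))
  hy <- build_embedding(con, one_module_spec(1, n + 1, 2 * n + 1),
                        G = 0.15, seed = 10)
  samp <- hy$placements$IT$coupling_samples    # 124 x 81 > 1e4 draws
  expect_gt(length(samp), 1e4)
  expect_lt(abs(mean(samp) - 0.15 / 81) / (0.15 / 81), 0.05)
})

test_that("embedding preserves every original connectome edge exactly", {
  con <- synthesize_connectome(n_nodes = 96, density = 0.12, seed = 21)
  hy <- suppressWarnings(
    build_embedding(con, G = 0.15, host_collision = "next", seed = 22))
  expect_identical(hy$connectome$weights, con$weights)
  # afferent completeness: in-neighbours of the host, exactly
  for (p in hy$placements) {
    expect_identical(p$afferents, which(con$weights[, p$host] > 0))
    expect_equal(p$structural_weights,
                 unname(con$weights[p$afferents, p$host]))
    # feedback created to exactly the afferent set, G * z / 81 per unit
    expect_equal(p$feedback_weights,
                 unname(con$weights[p$afferents, p$host]) / 81)
  }
})

test_that("host collisions error by default and fall over when allowed", {
  con <- star_connectome(leaves = 4)
  two <- rbind(one_module_spec(0, 0, 0, "IT"), one_module_spec(1, 0, 0, "FS"))
  expect_error(build_embedding(con, two, G = 0.15), "same host")
  expect_warning(
    build_embedding(con, two, G = 0.15, host_collision = "next", seed = 1),
    "next-nearest")
  hy <- suppressWarnings(
    build_embedding(con, two, G = 0.15, host_collision = "next", seed = 1))
  expect_equal(length(unique(vapply(hy$placements, `[[`, 0L, "host"))), 2)
})

test_that("a host with no in-edges yields an empty afferent set", {
  w <- matrix(0, 3, 3); w[1, 2] <- 0.5      # node 3 isolated
  con <- connectome(w, cbind(c(0, 10, 50), 0, 0))
  expect_warning(hy <- build_embedding(con, one_module_spec(50, 0, 0),
                                       G = 0.15, seed = 2),
                 "no afferent")
  p <- hy$placements$IT
  expect_length(p$afferents, 0)
  expect_length(p$feedback_weights, 0)
})

test_that("ROIs hold 81 units, the host, and k nearest non-host nodes", {
  hy <- small_hybrid()
  rois <- define_rois(hy, k = 5)
  hosts <- vapply(hy$placements, `[[`, 0L, "host")
  taken <- hosts                               # greedy-claim oracle
  for (nm in names(rois)) {
    r <- rois[[nm]]
    expect_length(r$units, 81)
    expect_length(r$nodes, 6)
    expect_equal(r$nodes[1], hy$placements[[nm]]$host)
    # brute-force k-nearest oracle over unclaimed non-host candidates
    d2 <- colSums((t(hy$connectome$coords) -
                     hy$placements[[nm]]$host_coords)^2)
    cand <- setdiff(order(d2), taken)
    expect_equal(r$nodes[-1], cand[1:5])
    taken <- c(taken, r$nodes[-1])
  }
  # membership is disjoint across ROIs
  all_nodes <- unlist(lapply(rois, `[[`, "nodes"))
  expect_equal(anyDuplicated(all_nodes), 0L)
  r0 <- define_rois(hy, k = 0)
  expect_length(r0$IT$nodes, 1)
  expect_error(define_rois(hy, k = -1), ">= 0")
})

test_that("region ROIs merge co-located populations", {
  hy <- small_hybrid()
  rr <- region_rois(hy, k = 5)
  expect_setequal(names(rr), c("V1", "V4", "IT", "FS", "D1", "D2", "FR"))
  expect_length(rr$V1$units, 162)             # V1h + V1v
  expect_length(rr$V4$units, 243)
  expect_length(rr$IT$units, 81)
})

test_that("the contralateral control ROI mirrors the IT host", {
  hy <- small_hybrid()
  cit <- contralateral_roi(hy, "IT", k = 5)
  expect_length(cit$units, 0)
  expect_length(cit$nodes, 6)
  hosts <- vapply(hy$placements, `[[`, 0L, "host")
  expect_false(any(cit$nodes %in% hosts))
  # mirrored x: the centre node sits in the opposite hemisphere
  expect_lt(hy$connectome$coords[cit$nodes[1], 1] *
              hy$placements$IT$host_coords[1], 0)
})

test_that("the embedding report tabulates placements", {
  hy <- small_hybrid()
  rep <- embedding_report(hy)
  expect_equal(nrow(rep), 10)
  expect_true(all(c("module", "host", "distance_mm", "n_afferents") %in%
                    names(rep)))
  expect_true(all(rep$distance_mm >= 0))
})
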