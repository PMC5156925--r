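test_that("identical seeds reproduce byte-identical datasets", {
  cfg <- simulation_config(n_positions = 120, seed = 17)
  d1 <- tempfile(); d2 <- tempfile()
  write_simulation(simulate_dataset(cfg), d1)
  write_simulation(simulate_dataset(cfg), d2)
  for (f in c("alnA_ctrl1.pu", "alnB_a3g3.pu", "genome.fa", "truth.tsv",
              "samples.tsv", "transcripts.tsv")) {
    expect_identical(readBin(file.path(d1, f), "raw", file.size(file.path(d1, f))),
                     readBin(file.path(d2, f), "raw", file.size(file.path(d2, f))),
                     label = f)
  }
  # a different seed changes the data
  d3 <- tempfile()
  write_simulation(simulate_dataset(simulation_config(n_positions = 120,
                                                      seed = 18)), d3)
  expect_false(identical(readLines(file.path(d1, "truth.tsv")),
                         readLines(file.path(d3, "truth.tsv"))))
})

test_that("the null configuration produces (almost) no calls", {
  sim <- simulate_dataset(simulation_config(n_positions = 500,
                                            fraction_edited = 0,
                                            strand_bias_artifact_fraction = 0,
                                            seed = 23))
  expect_false(any(sim$truth$is_edited))
  sites <- call_editing_sites(sim$profiles, sim$samples)
  expect_lte(nrow(sites), 1)
})

test_that("the noise-free limit concentrates treated levels at the truth", {
  sim <- simulate_dataset(simulation_config(
    n_positions = 150, error_rate = 0, sample_rho = 0, depth_mean = 400,
    level_shape = c(1, 1), level_range = c(0.2, 0.2), seed = 29))
  prof <- sim$profiles$alnA
  ctrl <- prof[prof$sample_id %in% c("ctrl1", "ctrl2", "ctrl3"), ]
  # control variant calls exactly zero everywhere
  edited_pos <- sim$truth$pos[sim$truth$is_edited]
  for (i in seq_len(nrow(ctrl))) {
    if (!ctrl$pos[i] %in% edited_pos) next
    vb <- c(A = "G", C = "T", G = "A", T = "C")[[ctrl$ref[i]]]
    expect_equal(ctrl[[paste0(vb, "_fwd")]][i] + ctrl[[paste0(vb, "_rev")]][i], 0)
  }
  sites <- call_editing_sites(sim$profiles, sim$samples)
  tp <- sites$pos %in% edited_pos
  expect_gt(sum(tp), 10)
  expect_lt(max(abs(sites$edit_level[tp] - 0.2)), 0.08)
})

test_that("control-group variant levels converge to the error rate", {
  sim <- simulate_dataset(simulation_config(
    n_positions = 300, fraction_edited = 0, depth_mean = 10000,
    depth_size = 50, strand_bias_artifact_fraction = 0, seed = 31))
  prof <- sim$profiles$alnA
  tr <- c(A = "G", C = "T", G = "A", T = "C")
  lv <- vapply(seq_len(nrow(prof)), function(i) {
    vb <- tr[[prof$ref[i]]]
    v <- prof[[paste0(vb, "_fwd")]][i] + prof[[paste0(vb, "_rev")]][i]
    rb <- prof$ref[i]
    r <- prof[[paste0(rb, "_fwd")]][i] + prof[[paste0(rb, "_rev")]][i]
    v / (v + r)
  }, numeric(1))
  expect_equal(mean(lv), 0.002, tolerance = 0.05)
})

test_that("the scorer agrees with a hand-counted fixture", {
  truth <- data.frame(chrom = "c", pos = 1:10,
                      is_edited = c(TRUE, TRUE, TRUE, TRUE, rep(FALSE, 6)),
                      true_level = c(0.2, 0.1, 0.3, 0.05, rep(NA, 6)),
                      strand = "+", artifact = FALSE, mean_depth = 100)
  called <- data.frame(chrom = "c", pos = c(1, 2, 7),
                       edit_level = c(0.25, 0.12, 0.08))
  sc <- score_calls(called, truth)
  expect_equal(sc$sensitivity, 2 / 4)
  expect_equal(sc$fdr, 1 / 3)
  expect_equal(sc$level_mae, mean(c(0.05, 0.02)))
  # restricted denominator
  sc2 <- score_calls(called, truth, level_min = 0.1)
  expect_equal(sc2$sensitivity, 2 / 3)
  # degenerate cases
  expect_equal(score_calls(called[0, ], truth)$sensitivity, 0)
  expect_equal(score_calls(called[0, ], truth)$fdr, 0)
  perfect <- data.frame(chrom = "c", pos = 1:4,
                        edit_level = c(0.2, 0.1, 0.3, 0.05))
  scp <- score_calls(perfect, truth)
  expect_equal(scp$sensitivity, 1)
  expect_equal(scp$fdr, 0)
  expect_equal(scp$level_mae, 0)
})

test_that("the strand-bias gate removes planted artifacts", {
  sim <- simulate_dataset(simulation_config(
    n_positions = 600, strand_bias_artifact_fraction = 0.05, seed = 37))
  art_pos <- sim$truth$pos[sim$truth$artifact]
  expect_gt(length(art_pos), 10)
  with_gate <- call_editing_sites(sim$profiles, sim$samples)
  no_gate <- call_editing_sites(sim$profiles, sim$samples,
                                filter_thresholds(strand_alpha = 0))
  surv_with <- sum(with_gate$pos %in% art_pos)
  surv_without <- sum(no_gate$pos %in% art_pos)
  expect_gt(surv_without, length(art_pos) * 0.5)
  expect_lt(surv_with, surv_without * 0.2)
})

test_that("planted contexts and stem-loops shape the reference windows", {
  sim <- simulate_dataset(simulation_config(n_positions = 800, seed = 41))
  tr_pos <- sim$truth[sim$truth$is_edited, ]
  wins <- vapply(tr_pos$pos, function(p)
    extract_window(sim$genome, "sim1", p, "+"), character(1))
  nb <- neighbor_distribution(wins)
  expect_gt(nb[["C"]] / sum(nb), 0.75)
  arms <- vapply(wins, function(w) find_inverted_repeat(w)$arm_length,
                 integer(1))
  expect_gt(mean(arms >= 3), 0.9)
  lm <- lapply(wins, call_loop_model)
  expect_gt(mean(vapply(lm, `[[`, integer(1), "arm_length") >= 2), 0.9)
})

test_that("infeasible configurations are rejected", {
  expect_error(simulation_config(fraction_edited = 1.5), "\\[0, 1\\]")
  expect_error(simulation_config(depth_mean = -1), "positive")
  expect_error(simulation_config(n_positions = 0), "n_positions")
})
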