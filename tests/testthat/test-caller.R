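# Hand-constructed profiles exercising individual gates of the cascade.

make_profiles <- function(ctrl_var, treat_var, depth = 100, ref = "C",
                          var = "T", chrom = "chr1", pos = 500,
                          fwd_frac_var = 0.5, other = 0) {
  mk <- function(vcounts) {
    do.call(rbind, lapply(seq_along(vcounts), function(s) {
      v <- vcounts[s]
      vf <- round(v * fwd_frac_var); vr <- v - vf
      oth <- setdiff(c("A", "C", "G", "T"), c(ref, var))[1]
      rf <- depth - v - other
      row <- data.frame(chrom = chrom, pos = pos, ref = ref,
                        sample_id = names(vcounts)[s],
                        A_fwd = 0L, C_fwd = 0L, G_fwd = 0L, T_fwd = 0L,
                        A_rev = 0L, C_rev = 0L, G_rev = 0L, T_rev = 0L,
                        stringsAsFactors = FALSE)
      row[[paste0(ref, "_fwd")]] <- floor(rf / 2)
      row[[paste0(ref, "_rev")]] <- rf - floor(rf / 2)
      row[[paste0(var, "_fwd")]] <- row[[paste0(var, "_fwd")]] + vf
      row[[paste0(var, "_rev")]] <- row[[paste0(var, "_rev")]] + vr
      row[[paste0(oth, "_fwd")]] <- row[[paste0(oth, "_fwd")]] + other
      row
    }))
  }
  counts <- c(ctrl_var, treat_var)
  names(counts) <- c(paste0("c", seq_along(ctrl_var)),
                     paste0("t", seq_along(treat_var)))
  prof <- mk(counts)
  list(alnA = prof, alnB = prof)
}

sheet3 <- data.frame(sample_id = c("c1", "c2", "c3", "t1", "t2", "t3"),
                     group = rep(c("control", "treated"), each = 3),
                     stringsAsFactors = FALSE)

test_that("a clean group-specific site passes every gate", {
  prof <- make_profiles(c(0, 0, 0), c(20, 22, 18))
  sites <- call_editing_sites(prof, sheet3)
  expect_equal(nrow(sites), 1)
  expect_equal(sites$edit_level, 0.20, tolerance = 0.01)
  expect_equal(sites$variant_base, "T")
  expect_lt(sites$p_adjusted, 0.05)
})

test_that("sites below the treated-mean threshold are rejected at the specificity gate", {
  prof <- make_profiles(c(0, 0, 0), c(3, 3, 3))   # treated mean 0.03 < 0.04
  sites <- call_editing_sites(prof, sheet3)
  expect_equal(nrow(sites), 0)
})

test_that("any control-sample variant signal vetoes the site", {
  prof <- make_profiles(c(2, 2, 2), c(20, 22, 18))  # control levels 0.02
  sites <- call_editing_sites(prof, sheet3)
  expect_equal(nrow(sites), 0)
  gs <- attr(sites, "gate_summary")
  expect_equal(gs$alnA[gs$gate == "group_specific"], 0)
})

test_that("other-base contamination is rejected", {
  prof <- make_profiles(c(0, 0, 0), c(20, 22, 18), other = 2)
  expect_equal(nrow(call_editing_sites(prof, sheet3)), 0)
})

test_that("low depth in any sample fails the depth gate", {
  prof <- make_profiles(c(0, 0, 0), c(2, 2, 2), depth = 5)
  sites <- call_editing_sites(prof, sheet3)
  gs <- attr(sites, "gate_summary")
  expect_equal(gs$alnA[gs$gate == "depth"], 0)
})

test_that("discordant aligner datasets yield no call", {
  prof <- make_profiles(c(0, 0, 0), c(20, 22, 18))
  profB <- prof
  profB$alnB[profB$alnB$sample_id %in% c("t1", "t2", "t3"),
             c("T_fwd", "T_rev")] <- 0L
  sites <- call_editing_sites(profB, sheet3)
  expect_equal(nrow(sites), 0)
})

test_that("one-directional variant calls fail the strand-bias gate", {
  prof <- make_profiles(c(0, 0, 0), c(20, 22, 18), fwd_frac_var = 1)
  sites <- call_editing_sites(prof, sheet3)
  expect_equal(nrow(sites), 0)
  gs <- attr(sites, "gate_summary")
  expect_equal(gs$alnA[gs$gate == "group_specific"], 1)
  expect_equal(gs$alnA[gs$gate == "strand_bias"], 0)
})

test_that("strand-bias gate applicability follows the count and skew rules", {
  th <- filter_thresholds()
  balanced <- strand_bias_gate(c(ref_fwd = 50, ref_rev = 50,
                                 var_fwd = 10, var_rev = 10), th)
  expect_equal(balanced$status, "not_applicable")
  skewed <- strand_bias_gate(c(ref_fwd = 50, ref_rev = 50,
                               var_fwd = 20, var_rev = 0), th)
  p_oracle <- oracle_fisher_p(matrix(c(50, 50, 20, 0), 2, byrow = TRUE))
  expect_equal(skewed$p, p_oracle)
  expect_equal(skewed$status, if (p_oracle < 0.05) "fail" else "pass")
  tiny <- strand_bias_gate(c(ref_fwd = 50, ref_rev = 50,
                             var_fwd = 7, var_rev = 0), th)
  expect_equal(tiny$status, "not_applicable")
})

test_that("edit types complement-and-relabel on the minus strand", {
  expect_equal(assign_edit_type("C", "T", "+"), "C>U")
  expect_equal(assign_edit_type("G", "A", "-"), "C>U")
  expect_equal(assign_edit_type("A", "G", "+"), "A>G")
  expect_equal(assign_edit_type("T", "C", "-"), "A>G")
})

test_that("site summaries count levels and types correctly", {
  sites <- data.frame(edit_level = c(0.10, 0.25, 0.35),
                      edit_type = c("C>U", "C>U", "C>U"))
  sm <- summarize_sites(sites)
  expect_equal(sm$n_sites, 3)
  expect_equal(unname(sm$n_above["gt_0.2"]), 2L)
  expect_equal(unname(sm$n_above["gt_0.3"]), 1L)
  # two-pass mean/sd agree with an independent accumulation (Welford)
  set.seed(4)
  lv <- runif(500)
  welford <- local({
    m <- 0; s2 <- 0
    for (i in seq_along(lv)) {
      d <- lv[i] - m; m <- m + d / i; s2 <- s2 + d * (lv[i] - m)
    }
    c(m, sqrt(s2 / (length(lv) - 1)))
  })
  sm2 <- summarize_sites(data.frame(edit_level = lv, edit_type = "C>U"))
  expect_equal(sm2$mean_level, welford[1], tolerance = 1e-12)
  expect_equal(sm2$sd_level, welford[2], tolerance = 1e-12)
  # empty input
  sm0 <- summarize_sites(data.frame(edit_level = numeric(0),
                                    edit_type = character(0)))
  expect_equal(sm0$n_sites, 0)
  expect_true(is.na(sm0$mean_level))
})

test_that("sample order within a group does not change the calls", {
  sim <- small_sim(seed = 31, n = 300)
  sites1 <- call_editing_sites(sim$profiles, sim$samples)
  perm <- sim$samples[c(2, 3, 1, 5, 6, 4), ]
  sites2 <- call_editing_sites(sim$profiles, perm)
  cols <- c("chrom", "pos", "variant_base", "edit_level", "p_adjusted")
  expect_equal(as.data.frame(sites1)[cols], as.data.frame(sites2)[cols],
               ignore_attr = TRUE)
})

test_that("swapping group labels on mirrored data mirrors the call set", {
  profA <- make_profiles(c(0, 0, 0), c(20, 22, 18))
  swapped <- data.frame(sample_id = sheet3$sample_id,
                        group = rev(sheet3$group))
  # control-labelled samples now carry the signal: no call either way
  expect_equal(nrow(call_editing_sites(profA, swapped)), 0)
  # but relabeling the mirrored construction reproduces the original call
  profM <- make_profiles(c(20, 22, 18), c(0, 0, 0))
  sitesM <- call_editing_sites(profM, swapped)
  sites0 <- call_editing_sites(profA, sheet3)
  expect_equal(nrow(sitesM), 1)
  expect_equal(sitesM$edit_level, sites0$edit_level)
})

test_that("relaxing single thresholds never removes called sites", {
  sim <- small_sim(seed = 41, n = 400)
  base_th <- filter_thresholds()
  base_sites <- call_editing_sites(sim$profiles, sim$samples, base_th)
  relaxations <- list(
    filter_thresholds(min_treated_mean_level = 0.02),
    filter_thresholds(final_min_edit_level = 0.03),
    filter_thresholds(alpha_adjusted = 0.10),
    filter_thresholds(min_calls_per_sample = 3),
    filter_thresholds(min_range_over_mean = 1),
    filter_thresholds(max_other_base_count_per_sample = 3),
    filter_thresholds(strand_alpha = 0.01))
  for (th in relaxations) {
    relaxed <- call_editing_sites(sim$profiles, sim$samples, th)
    expect_gte(nrow(relaxed), nrow(base_sites))
    expect_true(all(paste(base_sites$chrom, base_sites$pos) %in%
                    paste(relaxed$chrom, relaxed$pos)))
  }
})
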