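# Pairing combinatorics, rank-sum inference, multiple-testing adjustment,
# gastric stability, and the study-level analysis.

test_that("pairing counts follow S*r matched and S*r*(S-1)*r mismatched", {
  p <- build_pairings(toy_manifest(2, 2))
  expect_equal(nrow(p$matched), 4L)
  expect_equal(nrow(p$mismatched), 8L)
  p2 <- build_pairings(toy_manifest(3, 1))
  expect_equal(nrow(p2$matched), 3L)
  expect_equal(nrow(p2$mismatched), 6L)

  for (S in 2:5) {
    for (r in 1:3) {
      m <- toy_manifest(S, r)
      plan <- build_pairings(m)
      # brute-force enumeration over all ordered pairs
      n_mm <- 0L
      for (i in seq_len(nrow(m))) {
        for (j in seq_len(nrow(m))) {
          if (m$session_date[i] != m$session_date[j]) n_mm <- n_mm + 1L
        }
      }
      expect_equal(nrow(plan$matched), S * r)
      expect_equal(nrow(plan$mismatched), n_mm)
      expect_equal(n_mm, S * r * (S - 1) * r)
      # no mismatched pair ever shares a session date
      di <- m$session_date[match(plan$mismatched$rsn_run, m$run_id)]
      dj <- m$session_date[match(plan$mismatched$egg_run, m$run_id)]
      expect_true(all(di != dj))
      expect_false(any(duplicated(plan$mismatched)))
    }
  }
})

test_that("excluded runs and single-day manifests are handled", {
  m <- toy_manifest(3, 2)
  m$included[m$session == 3] <- FALSE
  m$exclusion_reason[m$session == 3] <- "weak gastric signal"
  p <- build_pairings(m)
  expect_equal(nrow(p$matched), 4L)
  expect_equal(nrow(p$mismatched), 8L)
  expect_error(build_pairings(toy_manifest(1, 2)), "2 distinct days")
})

test_that("the rank-sum test separates extremes and degrades gracefully", {
  set.seed(31)
  mismatched <- runif(1368, 0, 0.4)
  matched <- runif(38, 0.5, 1)
  expect_lt(sync_test(matched, mismatched), 1e-6)
  expect_warning(p <- sync_test(rep(0.2, 5), rep(0.2, 50)), "degenerate")
  expect_equal(p, 1)
  expect_error(sync_test(numeric(0), 1), "non-empty")
  # two-sided option
  expect_gte(sync_test(matched, mismatched, sided = "two"), 0)
})

test_that("rank-sum rejection rate is nominal under the null", {
  set.seed(32)
  rejections <- replicate(2000, {
    pool <- rbeta(80, 2, 8)
    sync_test(pool[1:16], pool[17:80]) < 0.05
  })
  expect_gt(mean(rejections), 0.03)
  expect_lt(mean(rejections), 0.07)
})

test_that("BH and Bonferroni adjustments obey dominance and monotonicity", {
  tab <- example_sync_table()
  adj <- bh_adjust(tab$p_uncorrected)
  expect_true(all(adj$p_adjusted >= tab$p_uncorrected))
  bon <- bonferroni_adjust(tab$p_uncorrected)
  expect_true(all(bon >= adj$p_adjusted - 1e-12))
  expect_true(all(bon <= 1))
  # adjusted sequence is monotone in rank order of the raw p-values
  o <- order(tab$p_uncorrected)
  expect_true(all(diff(adj$p_adjusted[o]) >= -1e-12))
  # identities and caps
  expect_equal(bh_adjust(0.03)$p_adjusted, 0.03)
  expect_equal(bonferroni_adjust(0, m = 18), 0)
  expect_equal(bonferroni_adjust(0.2, m = 18), 1)
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("gastric stability partitions pairs by day and detects day-specific rhythms", {
  # 3 sessions x 2 runs: day-specific frequencies, tight within-run stability
  set.seed(33)
  freqs <- c(0.044, 0.050, 0.056)
  gs <- list()
  for (s in 1:3) {
    for (r in 1:2) {
      id <- sprintf("S%dR%d", s, r)
      gs[[id]] <- tone_gastric(freqs[s], run_id = id,
                               date = as.Date("2019-07-01") + 2 * (s - 1),
                               phase0 = runif(1, -pi, pi))
    }
  }
  st <- gastric_stability(gs)
  expect_equal(st$n_same, 3L)          # C(6,2) = 15 pairs, 3 same-day
  expect_equal(st$n_different, 12L)
  expect_gt(mean(st$same_day), mean(st$different_day))
  expect_lt(st$p_value, 0.05)

  # tuning-fork limit: one exact frequency and phase everywhere -> all PLVs 1,
  # the comparison collapses and cannot be significant
  gs_tf <- lapply(gs, function(g) { g2 <- tone_gastric(0.05, run_id = g$run_id,
                                                       date = g$session_date); g2 })
  expect_warning(st_tf <- gastric_stability(gs_tf), "degenerate")
  expect_equal(st_tf$p_value, 1)
  expect_equal(mean(st_tf$same_day), 1, tolerance = 1e-6)
  expect_equal(mean(st_tf$different_day), 1, tolerance = 1e-6)

  one_per_day <- gs[c("S1R1", "S2R1", "S3R1")]
  expect_error(gastric_stability(one_per_day), "no same-day")
})

test_that("the full analysis is deterministic and excludes weak runs", {
  set.seed(34)
  bundle <- synthesize_study(fast_config(n_sessions = 3, seed = 77))
  # sabotage one run's EGG with pure noise -> weak verdict -> excluded
  bundle$runs[["S02R1"]]$egg$samples <- matrix(rnorm(9000 * 3), ncol = 3)
  res <- analyze_study(bundle)
  expect_s3_class(res, "sync_analysis")
  expect_false(res$manifest$included[res$manifest$run_id == "S02R1"])
  expect_match(res$manifest$exclusion_reason[res$manifest$run_id == "S02R1"],
               "weak")
  expect_equal(nrow(res$pairings$matched), 5L)
  expect_equal(nrow(res$table), 18L)
  expect_true(all(res$table$p_fdr >= res$table$p_uncorrected - 1e-12))
  expect_true(all(res$table$p_bonferroni >= res$table$p_fdr - 1e-12))
  expect_true(all(res$table$plv_mean >= 0 & res$table$plv_mean <= 1))

  res2 <- analyze_study(bundle)
  expect_identical(res$table, res2$table)
})
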