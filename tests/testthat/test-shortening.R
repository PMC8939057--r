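# a minimal fabricated analysis object for candidate-ranking tests
mock_analysis <- function(items, map, fr, chisq_sig, dif_items, rc_pairs,
                          delta) {
  k <- length(items)
  R <- diag(k); dimnames(R) <- list(items, items)
  avg <- -1 / (k - 1)
  for (p in rc_pairs) {
    R[p[1], p[2]] <- R[p[2], p[1]] <- avg + 0.3
  }
  rc <- structure(list(
    matrix = R, average = avg, critical = avg + 0.2,
    flagged = if (length(rc_pairs)) data.frame(
      item_a = vapply(rc_pairs, `[`, "", 1),
      item_b = vapply(rc_pairs, `[`, "", 2),
      r = avg + 0.3, excess = 0.1) else
        data.frame(item_a = character(0), item_b = character(0),
                   r = numeric(0), excess = numeric(0))),
    class = "residual_correlations")
  fit <- structure(list(item_ids = items, delta = stats::setNames(delta, items),
                        subscale_map = map), class = "pcm_fit")
  report <- list(items = data.frame(item = items, fit_residual = fr,
                                    chisq_significant = chisq_sig),
                 residual_correlations = rc)
  dif <- if (length(dif_items)) {
    d <- data.frame(item = dif_items, factor = "gender",
                    uniform_flag = TRUE, nonuniform_flag = FALSE)
    class(d) <- c("dif_table", "data.frame"); d
  }
  list(fit = fit, report = report, dif = dif)
}

test_that("candidates are ranked by indicator count with documented tie-breaks", {
  items <- c("E1", "E2", "E3", "E4", "M1", "M2", "M3", "M4")
  map <- stats::setNames(rep(c("EX", "MD"), each = 4), items)
  an <- mock_analysis(items, map,
                      fr = c(3.1, 0.2, -0.1, 0.5, 0.1, -0.2, 0.3, 0.2),
                      chisq_sig = c(TRUE, rep(FALSE, 7)),
                      dif_items = "E1",
                      rc_pairs = list(c("M1", "M2")),
                      delta = c(-0.9, -0.3, 0.1, 0.5, -0.5, -0.45, 0.3, 0.8))
  cfg <- shortening_config(content_flags = stats::setNames(
    c(4, 1, 1, 1, 1, 1, 1, 1), items))
  cands <- flag_elimination_candidates(an, cfg)
  # E1 fires on fit residual, chi-square, DIF and content: first in EX
  expect_equal(cands$EX$item[1], "E1")
  expect_equal(cands$EX$score[1], 4)
  expect_match(cands$EX$indicators[1], "fit_residual")
  expect_match(cands$EX$indicators[1], "dif")
  expect_match(cands$EX$indicators[1], "content")
  # the locally dependent pair leads MD; M1 and M2 tie on score and
  # correlation excess, so location redundancy decides (M1 vs M2 distance
  # is equal; stable order keeps M1 first)
  expect_true(cands$MD$item[1] %in% c("M1", "M2"))
  expect_equal(cands$MD$score[1:2], c(1, 1))
  # protection down-weights
  cfg2 <- shortening_config(protected = "E1", protect_weight = 10,
                            content_flags = cfg$content_flags)
  cands2 <- flag_elimination_candidates(an, cfg2)
  expect_false(cands2$EX$item[1] == "E1")
})

test_that("clean rosters fall through to the location-redundancy tie-break", {
  items <- paste0("X", 1:4)
  map <- stats::setNames(rep("EX", 4), items)
  an <- mock_analysis(items, map, fr = c(0.1, -0.2, 0.3, 0),
                      chisq_sig = rep(FALSE, 4), dif_items = character(0),
                      rc_pairs = list(), delta = c(-1, -0.1, 0, 1))
  cands <- flag_elimination_candidates(an, shortening_config())
  expect_true(all(cands$EX$score == 0))
  # X2 and X3 are 0.1 apart: most redundant pair leads the ranking
  expect_true(cands$EX$item[1] %in% c("X2", "X3"))
})

test_that("elimination steps respect the subscale floor and immutability", {
  resp <- sim_bat_like(300, seed = 17)
  cfg <- shortening_config(dif_factors = character(0))
  state <- list(resp = resp, config = cfg)
  state$analysis <- raschshort:::analyze_roster(resp, cfg, "SCALE23")
  sel <- c(EX = "EX1", MD = "MD1", CI = "CI1", EI = "EI1")
  st2 <- execute_elimination_step(state, sel)
  expect_equal(length(st2$resp$item_ids), 19L)
  # raw responses of surviving items untouched
  expect_identical(st2$resp$scores[, "EX2"], resp$scores[, "EX2"])
  expect_error(execute_elimination_step(state, c(EX = "MD1")), "not in subscale")
  # cannot take a 3-item subscale below the minimum
  small <- subset_items(resp, c(paste0("EX", 1:4), paste0("MD", 1:3),
                                paste0("CI", 1:3), paste0("EI", 1:3)))
  st3 <- list(resp = small, config = cfg)
  expect_error(execute_elimination_step(st3, c(MD = "MD1")), "below min_items")
})

test_that("the full pipeline follows the one-per-subscale schedule", {
  resp <- sim_bat_like(400, seed = 23)
  cfg <- shortening_config(dif_factors = character(0))
  tr <- suppressWarnings(run_shortening(resp, cfg))
  expect_equal(tr$roster_sizes, c(23L, 19L, 15L, 14L, 13L, 12L))
  expect_equal(length(tr$final_items), 12L)
  final_sizes <- table(resp$subscale_map[tr$final_items])
  expect_true(all(final_sizes == 3))
  # constraint safety at every step
  for (s in tr$steps)
    expect_true(all(table(resp$subscale_map[s$roster]) >= 3))
  # total chi-square df strictly decreases across steps
  dfs <- vapply(tr$steps, function(s) s$report$summary$chisq_df, 0)
  expect_true(all(diff(dfs) < 0))
  # a testlet analysis is appended
  expect_match(tr$testlet_report$label, "testlets")
  expect_s3_class(tr$conversion_table, "conversion_table")
  # determinism: identical rerun
  tr2 <- suppressWarnings(run_shortening(resp, cfg))
  expect_identical(tr2$final_items, tr$final_items)
  expect_identical(vapply(tr2$steps, function(s) s$report$summary$chisq, 0),
                   vapply(tr$steps, function(s) s$report$summary$chisq, 0))
})

test_that("cross-validation subsamples produce comparable traces", {
  resp <- sim_bat_like(1200, seed = 29)
  cfg <- shortening_config(dif_factors = character(0))
  subs <- stratified_subsample(resp, k_per_stratum = 100, n_draws = 2, seed = 30)
  traces <- lapply(subs, function(s) suppressWarnings(run_shortening(s, cfg)))
  for (tr in traces) {
    expect_equal(length(tr$final_items), 12L)
    expect_true(all(table(resp$subscale_map[tr$final_items]) == 3))
  }
})
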