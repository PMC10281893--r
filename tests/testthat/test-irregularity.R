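test_that("amplitude variability is the sample SD of cycle excursions", {
  expect_equal(amp_variability(fake_segmentation(rep(4, 5), p2p = rep(0.7, 5))), 0)
  # two-point closed form: sd(c(0.4, 0.6)) = sqrt(0.02)
  expect_equal(amp_variability(fake_segmentation(c(4, 4), p2p = c(0.4, 0.6))),
               sqrt(0.02), tolerance = 1e-12)
  expect_error(amp_variability(fake_segmentation(4, p2p = 1)),
               class = "insufficient_cycles")
})

test_that("amplitude variability recovers the generator parameter", {
  # 200 cycles, noise-free: estimate within 3 standard errors of 0.2
  g <- generate_signal(synthetic_spec(duration_s = 810, period_mean_s = 4,
                                      period_sd_s = 0.2, amp_sd = 0.2,
                                      seed = 21))
  a <- analyze_generated(g)
  est <- amp_variability(a$seg) * a$pp$provenance$scale
  n <- a$seg$n_cycles
  expect_gte(n, 195)
  expect_lt(abs(est - 0.2), 3 * 0.2 / sqrt(2 * (n - 1)))
})

test_that("the pause rule flags gaps of at least 1.5 mean cycles and no others", {
  # mean cycle 4 s, one 5 s gap: 5 < 6, not a pause
  seg <- fake_segmentation(c(4, 4, 5, 4, 4))
  expect_equal(nrow(detect_pauses(seg)), 0)

  # one 8 s gap qualifies (8 >= 1.5 * 4); start is the earlier peak
  seg2 <- fake_segmentation(c(4, 4, 8, 4, 4))
  p <- detect_pauses(seg2)
  expect_equal(p$duration_s, 8)
  expect_equal(p$start_s, 8)

  # boundary: exactly 1.5x counts as a pause
  seg3 <- fake_segmentation(c(4, 4, 6, 4, 4))
  expect_equal(detect_pauses(seg3)$duration_s, 6)
})

test_that("an inserted generator pause is detected with gap accounting", {
  g <- generate_signal(synthetic_spec(duration_s = 100, period_mean_s = 4,
                                      period_sd_s = 0.2, amp_sd = 0.1,
                                      noise_sd = 0.02,
                                      pauses = list(c(6, 10)), seed = 22))
  a <- analyze_generated(g)
  p <- detect_pauses(a$seg)
  expect_equal(nrow(p), 1)
  # the flagged gap spans the pause plus the interrupted cycle
  expect_lt(abs(p$duration_s - (10 + g$truth$periods_s[6])), 1 / 25 + 1e-9)
  m <- irregularity_metrics(a$seg, "c1")
  expect_equal(m$longest_pause_s, max(p$duration_s))
  # every reported pause satisfies the rule post hoc
  expect_true(all(p$duration_s >= 1.5 * a$seg$mean_cycle_s))
})

test_that("cohort selection ranks by the right statistic with disjoint lists", {
  # ids A..Z with amp SD equal to alphabet rank: top 15 are the last letters
  ms <- lapply(1:26, function(i)
    fake_metrics(LETTERS[i], amp_sd = i / 100, pause = (27 - i) / 10))
  sel <- select_irregular_cohort(ms, n_amp = 15, n_pause = 10)
  expect_equal(sort(sel$amp_selected), LETTERS[12:26])
  expect_equal(sel$amp_selected[1], "Z")
  # pause list drawn from the remaining curves only
  expect_length(intersect(sel$amp_selected, sel$pause_selected), 0)
  expect_equal(sel$pause_selected[1], "A")

  # a curve leading both rankings appears only in the amplitude list
  ms2 <- c(list(fake_metrics("best", amp_sd = 9, pause = 99)),
           lapply(1:30, function(i)
             fake_metrics(sprintf("c%02d", i), amp_sd = i / 100,
                          pause = i / 10)))
  sel2 <- select_irregular_cohort(ms2, n_amp = 5, n_pause = 5)
  expect_true("best" %in% sel2$amp_selected)
  expect_false("best" %in% sel2$pause_selected)

  expect_error(select_irregular_cohort(ms[1:10]), class = "size_error")
})

test_that("selection matches a brute-force sort oracle on random cohorts", {
  for (seed in 1:5) {
    set.seed(seed)
    ms <- lapply(1:40, function(i)
      fake_metrics(sprintf("r%02d", i), amp_sd = round(runif(1), 3),
                   pause = round(runif(1, 0, 15), 2)))
    sel <- select_irregular_cohort(ms, n_amp = 15, n_pause = 10)
    tab <- data.frame(id = sapply(ms, `[[`, "curve_id"),
                      amp = sapply(ms, `[[`, "amp_p2p_sd"),
                      pause = sapply(ms, `[[`, "longest_pause_s"))
    want_amp <- tab$id[order(-tab$amp, tab$id)][1:15]
    rest <- tab[!tab$id %in% want_amp, ]
    want_pause <- rest$id[order(-rest$pause, rest$id)][1:10]
    expect_equal(sel$amp_selected, want_amp)
    expect_equal(sel$pause_selected, want_pause)
  }
})

test_that("matching finds exact duplicates and nearest neighbours", {
  ms <- lapply(1:30, function(i)
    fake_metrics(sprintf("a%02d", i), amp_sd = i / 50, pause = i / 3))
  sel <- select_irregular_cohort(ms, n_amp = 4, n_pause = 3)
  # a pool of exact metric duplicates is matched at distance zero
  dup <- lapply(ms, function(m) {
    m$curve_id <- paste0("dup-", m$curve_id); m
  })
  mt <- match_cohorts(sel, dup)
  expect_equal(mt$pairs$metric_distance, rep(0, 7))
  expect_equal(mt$pairs$matched_id, paste0("dup-", mt$pairs$reference_id))

  # single reference 0.39 against pool 0.30/0.38/0.50 picks 0.38
  one <- select_irregular_cohort(
    list(fake_metrics("r", 0.39), fake_metrics("x", 0.1)),
    n_amp = 1, n_pause = 1)
  pool <- list(fake_metrics("p1", 0.30), fake_metrics("p2", 0.38),
               fake_metrics("p3", 0.50))
  got <- match_cohorts(one, pool)
  expect_equal(got$pairs$matched_id[got$pairs$reference_id == "r"], "p2")

  expect_error(match_cohorts(sel, ms[1:3]), class = "size_error")
})

test_that("greedy matching beats random assignment on total distance", {
  set.seed(33)
  ms <- lapply(1:30, function(i)
    fake_metrics(sprintf("a%02d", i), amp_sd = runif(1),
                 pause = runif(1, 0, 12)))
  pool <- lapply(1:30, function(i)
    fake_metrics(sprintf("b%02d", i), amp_sd = runif(1),
                 pause = runif(1, 0, 12)))
  sel <- select_irregular_cohort(ms, n_amp = 15, n_pause = 10)
  mt <- match_cohorts(sel, pool)
  expect_equal(anyDuplicated(mt$pairs$matched_id), 0)
  total <- sum(mt$pairs$metric_distance)

  ref_vals <- c(
    vapply(sel$amp_selected, function(id)
      sapply(ms, `[[`, "amp_p2p_sd")[match(id, sapply(ms, `[[`, "curve_id"))],
      numeric(1)),
    vapply(sel$pause_selected, function(id)
      sapply(ms, `[[`, "longest_pause_s")[match(id, sapply(ms, `[[`, "curve_id"))],
      numeric(1)))
  pool_amp <- sapply(pool, `[[`, "amp_p2p_sd")
  pool_pause <- sapply(pool, `[[`, "longest_pause_s")
  crit <- rep(c("amp", "pause"), c(15, 10))
  rand_totals <- replicate(1000, {
    perm <- sample(30, 25)
    sum(abs(ifelse(crit == "amp", pool_amp[perm], pool_pause[perm]) - ref_vals))
  })
  expect_true(all(total <= rand_totals))
})

test_that("cohort summaries compare medians and distributions", {
  ms <- lapply(1:12, function(i)
    fake_metrics(sprintf("a%02d", i), amp_sd = i / 30, pause = i))
  same <- cohort_summary(ms, ms)
  expect_equal(same$median_longest_pause_s[["a"]],
               same$median_longest_pause_s[["b"]])
  expect_equal(same$mw_amp$p_value, 1, tolerance = 0.05)

  shifted <- lapply(ms, function(m) {
    m$longest_pause_s <- m$longest_pause_s + 1; m
  })
  sh <- cohort_summary(ms, shifted)
  expect_equal(sh$median_longest_pause_s[["b"]] -
                 sh$median_longest_pause_s[["a"]], 1)
})
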