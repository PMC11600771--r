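mk_calls <- function(classes, marker_id = "M1") {
  data.frame(read_id = sprintf("r%03d", seq_along(classes)),
             marker_id = marker_id, call_class = classes,
             variant = ifelse(classes == "MUT", "mutA", NA),
             inserted_seq = "", arrival_index = seq_along(classes),
             stringsAsFactors = FALSE)
}

series_const <- function(vals) {
  # a VafSeries holding given running VAF values at n = 1..length
  structure(data.frame(n = seq_along(vals), vaf = vals),
            class = c("vaf_series", "data.frame"))
}

test_that("vaf_series tracks the running fraction in arrival order", {
  s <- vaf_series(mk_calls(c("MUT", "WT", "MUT")), "M1")
  expect_equal(s$n, 1:3)
  expect_equal(s$vaf, c(1, 0.5, 2 / 3))
  expect_equal(vaf_series(mk_calls(rep("WT", 5)), "M1")$vaf, rep(0, 5))
  calls <- mk_calls(c("MUT", "UNRECOGNIZABLE", "WT", "MUT"))
  expect_equal(nrow(vaf_series(calls, "M1")), 4)  # one point per call
  expect_equal(nrow(vaf_series(calls, "OTHER")), 0)
})

test_that("the Welch statistic, df and p match closed-form expectations", {
  r <- two_sample_t(c(0.2, 0.3), c(0.0, 0.1))
  expect_equal(r$t, 2.8284271, tolerance = 1e-6)
  expect_equal(r$df, 2, tolerance = 1e-9)
  expect_equal(r$p, 0.1055728, tolerance = 1e-6)

  # symmetry: swapping groups negates t, p unchanged
  r2 <- two_sample_t(c(0.0, 0.1), c(0.2, 0.3))
  expect_equal(r2$t, -r$t)
  expect_equal(r2$p, r$p)

  # degenerate conventions
  expect_equal(two_sample_t(c(1, 1), c(1, 1))$p, 1)
  expect_equal(two_sample_t(c(2, 2), c(1, 1))$p, 0)
  expect_error(two_sample_t(1, c(1, 2)), class = "amplisnv_input_error")
})

test_that("two_sample_t agrees with stats::t.test and the incomplete-beta oracle", {
  set.seed(55)
  for (k in 1:100) {
    a <- rnorm(sample(2:8, 1), mean = runif(1), sd = runif(1, 0.01, 2))
    b <- rnorm(sample(2:8, 1), mean = runif(1), sd = runif(1, 0.01, 2))
    mine <- two_sample_t(a, b)
    ref <- stats::t.test(a, b, var.equal = FALSE)
    expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$df, unname(ref$parameter), tolerance = 1e-10)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
    # independent t CDF via continued-fraction incomplete beta
    expect_equal(mine$p, oracle_t_p2(abs(mine$t), mine$df), tolerance = 1e-8)
  }
})

test_that("first and stable crossings follow their definitions", {
  cr <- ampliSNV:::first_stable_crossing(c(10, 20, 30, 40),
                                         c(0.2, 0.06, 0.04, 0.03), 0.05)
  expect_equal(cr$n_first, 30)
  expect_equal(cr$n_stable, 30)
  cr2 <- ampliSNV:::first_stable_crossing(c(10, 20, 30, 40),
                                          c(0.04, 0.2, 0.01, 0.01), 0.05)
  expect_equal(cr2$n_first, 10)
  expect_equal(cr2$n_stable, 30)
  cr3 <- ampliSNV:::first_stable_crossing(c(10, 20), c(0.9, 0.8), 0.05)
  expect_true(is.na(cr3$n_first) && is.na(cr3$n_stable))
})

test_that("threshold_scan aligns replicates on their own counts and skips sparse grid points", {
  a <- list(series_const(rep(0.30, 100)), series_const(rep(0.26, 100)),
            series_const(rep(0.28, 40)))              # third replicate shorter
  b <- list(series_const(rep(0.01, 100)), series_const(rep(0.02, 100)))
  ts <- threshold_scan(a, b, n_grid = c(20, 60, 100), marker_id = "M1")
  expect_s3_class(ts, "threshold_result")
  # at n = 20 all three variant replicates contribute; later only two
  expect_equal(ts$p_trace$n_a, c(3, 2, 2))
  expect_equal(ts$p_trace$n_b, c(3, 3, 3) - 1)
  # p at each evaluated point equals a direct Welch test on the same values
  direct <- two_sample_t(c(0.30, 0.26, 0.28), c(0.01, 0.02))$p
  expect_equal(ts$p_trace$p[1], direct)
  expect_equal(ts$n_first, 20)

  # a replicate group falling below 2 makes the grid point unevaluated
  short_b <- list(series_const(rep(0.01, 30)), series_const(rep(0.02, 30)))
  ts2 <- threshold_scan(a, short_b, n_grid = c(20, 60))
  expect_true(is.na(ts2$p_trace$p[2]))

  expect_error(threshold_scan(a[1], b, n_grid = 10),
               class = "amplisnv_input_error")
  expect_error(threshold_scan(a, b, n_grid = integer()),
               class = "amplisnv_input_error")
})

test_that("separated replicate groups cross significance quickly in the full pipeline", {
  p <- make_test_panel()
  ts <- marker_threshold_experiment(p, "M1", vaf = 0.25, reps = 3,
                                    n_reads = 120,
                                    error_model = error_model(0, 0, 0),
                                    seed = 61)
  expect_false(is.na(ts$n_first))
  expect_lt(ts$n_first, 80)
  expect_gte(ts$n_stable, ts$n_first)
})

test_that("larger effect sizes need no more reads on average", {
  p <- make_test_panel()
  n_first <- function(vaf, seed) {
    ts <- marker_threshold_experiment(p, "M1", vaf = vaf, reps = 2,
                                      n_reads = 150, seed = seed)
    if (is.na(ts$n_first)) 150 else ts$n_first
  }
  seeds <- 1:20
  hi <- vapply(seeds, function(s) n_first(0.25, s), 0)
  lo <- vapply(seeds, function(s) n_first(0.10, 1000 + s), 0)
  expect_lte(mean(hi), mean(lo))
})

test_that("identical wild-type groups rarely reach significance (sequential type-I check)", {
  # 3 replicates per group, the replicate count of the study designs; the
  # bound is deliberately loose because scanning for a first crossing
  # inflates the nominal alpha
  p <- make_test_panel()
  crossed <- vapply(1:40, function(s) {
    ts <- marker_threshold_experiment(p, "M1", vaf = 0, reps = 3,
                                      n_reads = 120,
                                      n_grid = seq(10, 120, by = 10),
                                      seed = 7000 + s)
    !is.na(ts$n_first)
  }, TRUE)
  expect_lte(mean(crossed), 0.15)
})

test_that("detection limit experiment finds the separable VAF under zero error", {
  p <- make_test_panel()
  dl <- detection_limit(p, c(0, 0.05), reps = 3, n_reads = 300,
                        error_model = error_model(0, 0, 0), seed = 71,
                        markers = "M1")
  expect_equal(dl$limits$limit[dl$limits$marker_id == "M1"], 0.05)
  expect_error(detection_limit(p, c(0.01, 0.05), seed = 1),
               class = "amplisnv_config_error")
})

test_that("threshold_reached applies the >= convention per marker", {
  p <- cns_panel()
  st <- new_tally(p)
  for (i in 1:85) {
    st <- update_tally(st, list(marker_id = "TERT_C250T",
                                call_class = if (i <= 55) "MUT" else "WT",
                                variant = if (i <= 55) "C250T" else NA,
                                arrival_index = i))
  }
  expect_true(threshold_reached(st, c(TERT_C250T = 77))[["TERT_C250T"]])
  expect_false(threshold_reached(st, c(IDH1_R132H = 45))[["IDH1_R132H"]])
  expect_true(threshold_reached(st, c(TERT_C250T = 85))[["TERT_C250T"]])
  expect_error(threshold_reached(st, c(NOPE = 5)),
               class = "amplisnv_input_error")
  expect_error(threshold_reached(st, c(TERT_C250T = 0)),
               class = "amplisnv_config_error")
})
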