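fake_rec <- function(cs, tstart, tend) {
  list(cs = cs, tstart = tstart, tend = tend)
}

test_that("the junction insertion is read off the alignment, with tolerance", {
  expect_equal(extract_locus_insertion(fake_rec(":250+T:249", 0, 499), 250), "T")
  # no coverage of the junction: not callable
  expect_null(extract_locus_insertion(fake_rec(":100", 0, 100), 250))
  # off-by-one placement absorbed by the default tolerance
  expect_equal(extract_locus_insertion(fake_rec(":249+T:250", 0, 499), 250), "T")
  expect_equal(extract_locus_insertion(fake_rec(":252+T:247", 0, 499), 250), "T")
  # beyond the tolerance the insertion is not attributed to the junction
  expect_equal(extract_locus_insertion(fake_rec(":249+T:250", 0, 499), 250,
                                       tol = 0), "")
  expect_equal(extract_locus_insertion(fake_rec(":240+T:259", 0, 499), 250), "")
  # a covered junction with no insertion yields an empty string
  expect_equal(extract_locus_insertion(fake_rec(":499", 0, 499), 250), "")
  # flank requirement: too few aligned bases on one side
  expect_null(extract_locus_insertion(fake_rec(":245+T:5", 0, 250), 245))
  # inconsistent coordinates are an error
  expect_error(extract_locus_insertion(fake_rec(":499", 0, 400), 250),
               class = "amplisnv_parse_error")
})

test_that("insertions classify as WT, named MUT, or UNRECOGNIZABLE", {
  mk <- marker_site("TERT_C250T", "TERT", 282, 1, "C", c(C250T = "T"))
  expect_equal(classify_call("T", mk)$call_class, "MUT")
  expect_equal(classify_call("T", mk)$variant, "C250T")
  expect_equal(classify_call("C", mk)$call_class, "WT")
  expect_equal(classify_call("G", mk)$call_class, "UNRECOGNIZABLE")
  expect_equal(classify_call("", mk)$call_class, "UNRECOGNIZABLE")
  expect_equal(classify_call("TT", mk)$call_class, "UNRECOGNIZABLE")
  expect_null(classify_call(NULL, mk))
})

test_that("tallies conserve counts and are order independent", {
  p <- cns_panel()
  st <- new_tally(p)
  st <- update_tally(st, list(marker_id = "TERT_C250T", call_class = "WT",
                              variant = NA, arrival_index = 1))
  expect_equal(st$TERT_C250T$n_wt, 1)
  expect_equal(st$TERT_C250T$n_total, 1)
  expect_error(update_tally(st, list(marker_id = "NOPE", call_class = "WT",
                                     variant = NA, arrival_index = 2)),
               class = "amplisnv_input_error")

  # the clinical-demonstrator arithmetic: 85 assigned reads, 55 mutant
  calls <- data.frame(
    read_id = sprintf("r%03d", 1:85), marker_id = "TERT_C250T",
    call_class = c(rep("MUT", 55), rep("WT", 25), rep("UNRECOGNIZABLE", 5)),
    variant = c(rep("C250T", 55), rep(NA, 30)),
    inserted_seq = "", arrival_index = 1:85, stringsAsFactors = FALSE)
  st2 <- tally_calls(calls, p)
  expect_equal(st2$TERT_C250T$n_total, 85)
  expect_equal(sum(st2$TERT_C250T$n_mut), 55)
  expect_equal(marker_vaf(st2, "TERT_C250T"), 55 / 85)
  expect_equal(round(100 * marker_vaf(st2, "TERT_C250T")), 65)

  # permuting the call multiset leaves the final counts unchanged
  set.seed(2)
  shuffled <- calls[sample(nrow(calls)), ]
  st3 <- tally_calls(shuffled, p)
  for (f in c("n_wt", "n_mut", "n_unrec", "n_total")) {
    expect_equal(st3$TERT_C250T[[f]], st2$TERT_C250T[[f]])
  }
  # one-by-one updates agree with the bulk tally
  st4 <- new_tally(p)
  for (i in seq_len(nrow(calls))) st4 <- update_tally(st4, calls[i, ])
  expect_equal(st4$TERT_C250T[c("n_wt", "n_mut", "n_unrec", "n_total")],
               st2$TERT_C250T[c("n_wt", "n_mut", "n_unrec", "n_total")])
})

test_that("marker_vaf handles edge cases and both denominators", {
  p <- cns_panel()
  st <- new_tally(p)
  expect_true(is.na(marker_vaf(st, "BRAF_V600E")))  # no data, no error
  st <- update_tally(st, list(marker_id = "BRAF_V600E", call_class = "MUT",
                              variant = "V600E", arrival_index = 1))
  expect_equal(marker_vaf(st, "BRAF_V600E"), 1.0)
  st <- update_tally(st, list(marker_id = "BRAF_V600E",
                              call_class = "UNRECOGNIZABLE", variant = NA,
                              arrival_index = 2))
  expect_equal(marker_vaf(st, "BRAF_V600E"), 0.5)
  expect_equal(marker_vaf(st, "BRAF_V600E", denominator = "called"), 1.0)
  expect_equal(marker_vaf(st, "BRAF_V600E", variant = "V600E"), 0.5)
  expect_error(marker_vaf(st, "BRAF_V600E", variant = "X"),
               class = "amplisnv_input_error")
})

test_that("zero-error reads are classified exactly to their true alleles", {
  p <- make_test_panel()
  run <- simulate_run(p, sample_profile(M1 = 0.4, M2a = 0.3, M2b = 0.2),
                      run_config(400, seed = 21, error_model = error_model(0, 0, 0)))
  res <- call_reads(run, p)
  expect_equal(res$n_unassigned, 0)

  # every read must be called at every marker of its amplicon, correctly
  truth <- run$truth
  for (mk in names(p$markers)) {
    sub <- res$calls[res$calls$marker_id == mk, ]
    expected <- truth[[mk]][!is.na(truth[[mk]])]
    expect_equal(nrow(sub), length(expected))
    got_variant <- ifelse(sub$call_class == "MUT", sub$variant, "WT")
    expect_equal(got_variant, expected)
    # measured VAF equals the truth-table fraction exactly
    fr <- truth_fraction(run, mk)
    mut_name <- names(p$markers[[mk]]$mut_alleles)
    truth_vaf <- if (mut_name %in% names(fr)) unname(fr[[mut_name]]) else 0
    expect_equal(marker_vaf(res$tally, mk), truth_vaf)
    # conservation: class counts sum to the number of emitted calls
    s <- res$tally[[mk]]
    expect_equal(s$n_wt + sum(s$n_mut) + s$n_unrec, s$n_total)
    expect_equal(s$n_total, nrow(sub))
  }
})

test_that("classification is invariant under reverse-complementing reads", {
  p <- make_test_panel()
  run <- simulate_run(p, sample_profile(M1 = 0.5),
                      run_config(60, weights = solo_weights(p, "AMP1"),
                                 seed = 13, strand_prob = 0))
  res_fwd <- call_reads(run$reads, p)
  res_rc <- call_reads(revcomp(run$reads), p)
  expect_equal(res_fwd$calls[c("marker_id", "call_class", "variant", "inserted_seq")],
               res_rc$calls[c("marker_id", "call_class", "variant", "inserted_seq")])
})

test_that("wild-type runs under the default error model stay below the false-positive ceiling", {
  p <- cns_panel()
  run <- simulate_run(p, wt_profile(),
                      run_config(800, weights = solo_weights(p, "TERT"),
                                 seed = 41))
  res <- call_reads(run, p)
  for (mk in c("TERT_C228T", "TERT_C250T")) {
    v <- marker_vaf(res$tally, mk)
    expect_lt(v, 0.04)  # empirical regression ceiling; typical values ~0.02
    # substitution errors at the junction mostly yield UNRECOGNIZABLE calls
    expect_gt(res$tally[[mk]]$n_unrec, sum(res$tally[[mk]]$n_mut))
  }
})

test_that("PAF import reproduces the FASTA path on the same alignments", {
  p <- make_test_panel()
  run <- simulate_run(p, sample_profile(M2a = 0.5, M2b = 0.3),
                      run_config(80, seed = 29))
  direct <- call_reads(run$reads, p, prefilter = FALSE, band = 0)
  recs <- do.call(rbind, lapply(seq_along(run$reads), function(i)
    align_read(run$reads[[i]], p$targets, read_id = names(run$reads)[i])))
  paf <- tempfile(fileext = ".paf")
  write_paf(recs, paf)
  via_paf <- call_paf(paf, p)
  expect_equal(via_paf$calls[c("read_id", "marker_id", "call_class",
                               "variant", "inserted_seq")],
               direct$calls[c("read_id", "marker_id", "call_class",
                              "variant", "inserted_seq")])
  for (mk in names(p$markers)) {
    expect_equal(via_paf$tally[[mk]], direct$tally[[mk]])
  }
})

test_that("banded pipeline calling equals the full dynamic program", {
  p <- make_test_panel()
  run <- simulate_run(p, sample_profile(M1 = 0.3), run_config(60, seed = 37))
  banded <- call_reads(run, p, band = "auto")
  full <- call_reads(run, p, band = 0)
  expect_equal(banded$calls, full$calls)
})
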