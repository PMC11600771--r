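#' Streaming VAF trajectory of a marker
#'
#' After each assigned call for the marker (in arrival order), records the
#' cumulative per-marker read count and the running variant allele fraction
#' under the [marker_vaf()] convention (all assigned calls, including
#' unrecognizable ones, in the denominator).
#'
#' @param calls an `"amplicall"` object or a locus-call data.frame sorted by
#'   `arrival_index`.
#' @param marker_id marker to trace.
#' @param variant optional variant name for a per-variant trajectory.
#' @return data.frame of class `"vaf_series"` with columns `n` (strictly
#'   increasing) and `vaf`; zero rows when the marker received no calls.
#' @export
vaf_series <- function(calls, marker_id, variant = NULL) {
  if (inherits(calls, "amplicall")) calls <- calls$calls
  sub <- calls[calls$marker_id == marker_id, , drop = FALSE]
  sub <- sub[order(sub$arrival_index), , drop = FALSE]
  is_mut <- if (is.null(variant)) {
    sub$call_class == "MUT"
  } else {
    sub$call_class == "MUT" & !is.na(sub$variant) & sub$variant == variant
  }
  out <- data.frame(n = seq_len(nrow(sub)),
                    vaf = if (nrow(sub)) cumsum(is_mut) / seq_len(nrow(sub))
                          else numeric())
  attr(out, "marker_id") <- marker_id
  class(out) <- c("vaf_series", "data.frame")
  out
}

#' Significance-testing configuration
#'
#' @param alpha significance level in (0, 1), default 0.05.
#' @param test only `"welch"` (unequal-variance two-sample t) is provided;
#'   replicate group sizes typically differ, and the pooled-variance variant
#'   gains nothing here.
#' @param sided only `"two"` (two-sided) is provided.
#' @return object of class `"stat_config"`.
#' @export
stat_config <- function(alpha = 0.05, test = "welch", sided = "two") {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    amplisnv_stop("alpha must lie in (0, 1)", "amplisnv_config_error")
  }
  test <- match.arg(test, "welch")
  sided <- match.arg(sided, "two")
  structure(list(alpha = alpha, test = test, sided = sided),
            class = "stat_config")
}

#' Welch two-sample t-test
#'
#' `t = (mean_a - mean_b) / sqrt(s2_a/n_a + s2_b/n_b)` with the
#' Welch-Satterthwaite degrees of freedom and a two-sided p-value from the t
#' distribution. Degenerate convention when both sample variances are zero:
#' p = 0 if the means differ, p = 1 if they are equal (the groups are then
#' perfectly separated, or indistinguishable).
#'
#' @param group_a,group_b numeric vectors, each of length >= 2.
#' @param cfg a [stat_config()].
#' @return list with `t`, `df`, `p`.
#' @export
two_sample_t <- function(group_a, group_b, cfg = stat_config()) {
  na <- length(group_a); nb <- length(group_b)
  if (na < 2L || nb < 2L) {
    amplisnv_stop("each group needs at least 2 values", "amplisnv_input_error")
  }
  ma <- mean(group_a); mb <- mean(group_b)
  va <- stats::var(group_a); vb <- stats::var(group_b)
  if (va == 0 && vb == 0) {
    return(list(t = if (ma == mb) 0 else sign(ma - mb) * Inf,
                df = na + nb - 2, p = if (ma == mb) 1 else 0))
  }
  se2 <- va / na + vb / nb
  tstat <- (ma - mb) / sqrt(se2)
  df <- se2^2 / (va^2 / (na^2 * (na - 1)) + vb^2 / (nb^2 * (nb - 1)))
  list(t = tstat, df = df, p = 2 * stats::pt(-abs(tstat), df))
}

# first crossing and suffix-stable crossing of p <= alpha over a p-trace
first_stable_crossing <- function(n, p, alpha) {
  sig <- !is.na(p) & p <= alpha
  n_first <- if (any(sig)) n[which(sig)[1L]] else NA_integer_
  n_stable <- NA_integer_
  if (any(sig)) {
    ok <- rev(cumprod(rev(as.integer(sig | is.na(p))))) == 1L
    # a trailing run must contain at least one evaluated point
    ok <- ok & rev(cummax(rev(as.integer(sig)))) == 1L
    if (any(ok)) n_stable <- n[which(ok)[1L]]
  }
  list(n_first = n_first, n_stable = n_stable)
}

# VAF of one replicate series at grid point n: value at the last cumulative
# count <= n; NA when the replicate has not yet accumulated n calls
series_at <- function(series, n_grid) {
  if (!nrow(series)) return(rep(NA_real_, length(n_grid)))
  idx <- findInterval(n_grid, series$n)
  v <- ifelse(idx >= 1L, series$vaf[pmax(idx, 1L)], NA_real_)
  v[n_grid > max(series$n)] <- NA_real_
  v
}

#' Read-count threshold for significant group separation
#'
#' Scans increasing per-marker cumulative read counts and asks, at each grid
#' point, whether the replicate VAFs of group A differ significantly from
#' those of group B (Welch test). Each replicate contributes its own VAF at
#' its own marker-specific cumulative count (the last value at or before the
#' grid point); replicates that have not yet accumulated that many calls are
#' excluded at that grid point, and the point is skipped when either group
#' drops below two replicates. Reports the first crossing `n_first`
#' (smallest n with p <= alpha), the suffix-stable crossing `n_stable`
#' (smallest n from which p <= alpha holds at every later evaluated point),
#' and the full p-trace.
#'
#' @param replicates_a,replicates_b lists of [vaf_series()] (>= 2 each).
#' @param n_grid increasing cumulative read counts to evaluate.
#' @param cfg a [stat_config()].
#' @param marker_id recorded on the result.
#' @return object of class `"threshold_result"`: `marker_id`, `n_first`,
#'   `n_stable`, `p_trace` (data.frame n, p, n_a, n_b), `alpha`.
#' @export
threshold_scan <- function(replicates_a, replicates_b, n_grid,
                           cfg = stat_config(), marker_id = NA_character_) {
  if (length(replicates_a) < 2L || length(replicates_b) < 2L) {
    amplisnv_stop("need at least 2 replicates per group", "amplisnv_input_error")
  }
  n_grid <- sort(unique(as.integer(n_grid)))
  if (!length(n_grid)) {
    amplisnv_stop("empty read-count grid", "amplisnv_input_error")
  }
  A <- vapply(replicates_a, series_at, numeric(length(n_grid)), n_grid = n_grid)
  B <- vapply(replicates_b, series_at, numeric(length(n_grid)), n_grid = n_grid)
  A <- matrix(A, nrow = length(n_grid)); B <- matrix(B, nrow = length(n_grid))
  p <- rep(NA_real_, length(n_grid))
  n_a <- integer(length(n_grid)); n_b <- integer(length(n_grid))
  for (i in seq_along(n_grid)) {
    a <- A[i, ][!is.na(A[i, ])]; b <- B[i, ][!is.na(B[i, ])]
    n_a[i] <- length(a); n_b[i] <- length(b)
    if (length(a) >= 2L && length(b) >= 2L) {
      p[i] <- two_sample_t(a, b, cfg)$p
    }
  }
  cr <- first_stable_crossing(n_grid, p, cfg$alpha)
  structure(list(marker_id = marker_id, n_first = cr$n_first,
                 n_stable = cr$n_stable,
                 p_trace = data.frame(n = n_grid, p = p, n_a = n_a, n_b = n_b),
                 alpha = cfg$alpha),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("Threshold scan%s (alpha = %g): n_first = %s, n_stable = %s over %d grid points\n",
              if (is.na(x$marker_id)) "" else paste0(" for ", x$marker_id),
              x$alpha,
              if (is.na(x$n_first)) "undefined" else x$n_first,
              if (is.na(x$n_stable)) "undefined" else x$n_stable,
              nrow(x$p_trace)))
  invisible(x)
}

# simulate one replicate run concentrated on one marker's amplicon and
# return its VAF series (full pipeline: simulate, align, classify)
simulate_marker_series <- function(panel, marker_id, vaf, n_reads, em,
                                   params = align_params()) {
  mk <- panel$markers[[marker_id]]
  prof <- if (vaf > 0) {
    sample_profile(.list = setNames(list(vaf), marker_id))
  } else wt_profile()
  w <- setNames(numeric(length(panel$amplicons)), names(panel$amplicons))
  w[mk$amplicon_id] <- 1
  run <- simulate_run(panel, prof,
                      run_config(n_reads, weights = w, error_model = em))
  res <- call_reads(run, panel, params = params)
  vaf_series(res, marker_id)
}

#' Replicate threshold experiment for one marker
#'
#' Simulates `reps` variant runs (true VAF `vaf`) and `reps` wild-type runs
#' on the marker's amplicon through the full
#' simulate-align-classify pipeline, then applies [threshold_scan()].
#'
#' @param panel an `"amplicon_panel"`.
#' @param marker_id marker to test.
#' @param vaf true variant allele fraction of the variant group.
#' @param reps replicates per group.
#' @param n_reads reads per replicate run.
#' @param n_grid cumulative-count grid (default every 5 reads up to
#'   `n_reads`).
#' @param cfg a [stat_config()].
#' @param error_model an [error_model()].
#' @param seed integer seed; the experiment is deterministic given it.
#' @return a `"threshold_result"`.
#' @export
marker_threshold_experiment <- function(panel, marker_id, vaf, reps = 3L,
                                        n_reads = 500L,
                                        n_grid = seq(5L, n_reads, by = 5L),
                                        cfg = stat_config(),
                                        error_model = ampliSNV::error_model(),
                                        seed = NULL) {
  with_preserved_seed(seed, {
    reps_a <- replicate(reps, simulate_marker_series(
      panel, marker_id, vaf, n_reads, error_model), simplify = FALSE)
    reps_b <- replicate(reps, simulate_marker_series(
      panel, marker_id, 0, n_reads, error_model), simplify = FALSE)
    threshold_scan(reps_a, reps_b, n_grid, cfg, marker_id = marker_id)
  })
}

#' Detection-limit experiment
#'
#' For each marker and each nonzero VAF on the grid, simulates `reps`
#' replicate runs at that VAF and compares them against `reps` wild-type
#' (0 % VAF) replicate runs with [threshold_scan()] over every cumulative
#' read count up to `n_reads`. The marker's detection limit is the smallest
#' grid VAF with a defined first crossing. The wild-type replicates are
#' simulated once per marker and reused across the grid; the whole
#' experiment is deterministic given `seed`.
#'
#' @param panel an `"amplicon_panel"`.
#' @param vaf_grid increasing fractions, starting at 0.
#' @param reps replicates per group (>= 2).
#' @param n_reads reads per replicate run.
#' @param cfg a [stat_config()].
#' @param error_model an [error_model()].
#' @param seed integer seed.
#' @param markers markers to test (default: all in the panel).
#' @return object of class `"detection_limit"`: data.frame `limits`
#'   (marker_id, limit — `NA` when no grid VAF separated), and the per-VAF
#'   `n_first` table `detail`.
#' @export
detection_limit <- function(panel, vaf_grid, reps = 3L, n_reads = 1000L,
                            cfg = stat_config(),
                            error_model = ampliSNV::error_model(),
                            seed = NULL, markers = names(panel$markers)) {
  vaf_grid <- sort(unique(vaf_grid))
  if (length(vaf_grid) < 2L || vaf_grid[1L] != 0) {
    amplisnv_stop("vaf_grid must start at 0 and contain a nonzero VAF",
                  "amplisnv_config_error")
  }
  if (reps < 2L) {
    amplisnv_stop("need at least 2 replicates", "amplisnv_input_error")
  }
  nonzero <- vaf_grid[vaf_grid > 0]
  n_grid <- seq_len(n_reads)
  with_preserved_seed(seed, {
    detail <- list()
    limits <- data.frame(marker_id = markers, limit = NA_real_,
                         stringsAsFactors = FALSE)
    for (mi in seq_along(markers)) {
      mk <- markers[mi]
      reps_b <- replicate(reps, simulate_marker_series(
        panel, mk, 0, n_reads, error_model), simplify = FALSE)
      for (v in nonzero) {
        reps_a <- replicate(reps, simulate_marker_series(
          panel, mk, v, n_reads, error_model), simplify = FALSE)
        ts <- threshold_scan(reps_a, reps_b, n_grid, cfg, marker_id = mk)
        detail[[length(detail) + 1L]] <- data.frame(
          marker_id = mk, vaf = v, n_first = ts$n_first,
          n_stable = ts$n_stable, stringsAsFactors = FALSE)
        if (is.na(limits$limit[mi]) && !is.na(ts$n_first)) {
          limits$limit[mi] <- v
        }
      }
    }
    structure(list(limits = limits, detail = do.call(rbind, detail),
                   vaf_grid = vaf_grid, reps = reps, n_reads = n_reads,
                   alpha = cfg$alpha),
              class = "detection_limit")
  })
}

#' @export
print.detection_limit <- function(x, ...) {
  cat(sprintf("Detection limits (alpha = %g, %d reps x %d reads, grid %s):\n",
              x$alpha, x$reps, x$n_reads,
              paste(sprintf("%g%%", 100 * x$vaf_grid), collapse = "/")))
  for (i in seq_len(nrow(x$limits))) {
    cat(sprintf("  %-14s %s\n", x$limits$marker_id[i],
                if (is.na(x$limits$limit[i])) "not reached"
                else sprintf("%g%%", 100 * x$limits$limit[i])))
  }
  invisible(x)
}

#' Reportability: have the preestablished read thresholds been reached?
#'
#' @param state a `"tally_state"`.
#' @param min_reads named integer vector marker_id -> required reads.
#' @return named logical: `TRUE` iff the marker's assigned-call total has
#'   reached its threshold (>= convention).
#' @export
threshold_reached <- function(state, min_reads) {
  unknown <- setdiff(names(min_reads), names(state))
  if (length(unknown)) {
    amplisnv_stop(sprintf("thresholds name unknown markers: %s",
                          paste(unknown, collapse = ", ")),
                  "amplisnv_input_error")
  }
  if (any(min_reads <= 0)) {
    amplisnv_stop("thresholds must be positive", "amplisnv_config_error")
  }
  vapply(names(min_reads), function(mk)
    state[[mk]]$n_total >= min_reads[[mk]], TRUE)
}

#' Export a p-trace as CSV
#' @param result a `"threshold_result"`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_p_trace <- function(result, path) {
  utils::write.csv(result$p_trace, path, row.names = FALSE)
  invisible(path)
}
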