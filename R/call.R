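#' Extract the artificial insertion at a modified target's junction
#'
#' Because the marker bases are deleted from the modified reference, a read
#' spanning the site aligns with an insertion at the deletion junction whose
#' sequence is the read's allele. This walks the alignment's difference
#' string, collects inserted bases whose target coordinate falls within
#' `tol` of the junction, and applies the flank requirement: the alignment
#' must cover `[junction - flank, junction + flank)` on the target with at
#' least `flank` aligned (match or mismatch) bases on each side of the
#' junction. Reads failing the requirement are not callable at this marker
#' (they contribute no call at all, rather than an unrecognizable one).
#'
#' @param record single alignment record (row of [align_read()] output) whose
#'   target is the marker's modified target.
#' @param target a `"modified_target"` (supplies the junction), or a junction
#'   position given directly as a number.
#' @param flank minimum aligned reference bases required on each side.
#' @param tol junction attribution tolerance in target bases (default 2):
#'   aligners may shift an insertion within locally repetitive context.
#' @return the inserted DNA string (possibly `""` when the site is covered
#'   but no base was inserted), or `NULL` when the read is not callable.
#' @export
extract_locus_insertion <- function(record, target, flank = 10L, tol = 2L) {
  junction <- if (is.numeric(target)) as.integer(target) else target$junction
  out <- tryCatch(
    extract_cs_insertion_cpp(record$cs, record$tstart, record$tend,
                             junction, flank, tol),
    error = function(e) amplisnv_stop(conditionMessage(e), "amplisnv_parse_error"))
  if (is.na(out)) NULL else out
}

#' Classify an observed junction insertion
#'
#' @param inserted_seq the inserted DNA string from
#'   [extract_locus_insertion()] (possibly `""`), or `NULL` for a
#'   not-callable read.
#' @param marker a [marker_site()].
#' @return `NULL` when not callable; otherwise a list with `call_class`
#'   (`"WT"`, `"MUT"` or `"UNRECOGNIZABLE"`), `variant` (variant name for
#'   MUT, else `NA`) and `inserted_seq`. An empty insertion (the allele base
#'   was lost to a deletion error) and any unexpected string classify as
#'   UNRECOGNIZABLE: the site was covered but uninterpretable.
#' @export
classify_call <- function(inserted_seq, marker) {
  if (is.null(inserted_seq)) return(NULL)
  if (identical(inserted_seq, marker$wt_allele)) {
    return(list(call_class = "WT", variant = NA_character_,
                inserted_seq = inserted_seq))
  }
  hit <- which(marker$mut_alleles == inserted_seq)
  if (length(hit) == 1L) {
    return(list(call_class = "MUT", variant = names(marker$mut_alleles)[hit],
                inserted_seq = inserted_seq))
  }
  list(call_class = "UNRECOGNIZABLE", variant = NA_character_,
       inserted_seq = inserted_seq)
}

empty_calls <- function() {
  data.frame(read_id = character(), marker_id = character(),
             call_class = character(), variant = character(),
             inserted_seq = character(), arrival_index = integer(),
             stringsAsFactors = FALSE)
}

#' Create an empty per-marker tally
#'
#' @param panel an `"amplicon_panel"`.
#' @return object of class `"tally_state"`: per marker, wild-type count,
#'   per-variant mutant counts, unrecognizable count, total, and the last
#'   arrival index seen.
#' @export
new_tally <- function(panel) {
  st <- lapply(panel$markers, function(mk) {
    list(n_wt = 0L,
         n_mut = setNames(integer(length(mk$mut_alleles)), names(mk$mut_alleles)),
         n_unrec = 0L, n_total = 0L, last_arrival = NA_integer_)
  })
  structure(st, class = "tally_state")
}

#' Add one locus call to a tally
#'
#' Exactly one counter is incremented and the marker total grows by one;
#' final counts are independent of call order.
#'
#' @param state a `"tally_state"`.
#' @param call a one-row data.frame or list with `marker_id`, `call_class`,
#'   `variant`, `arrival_index`.
#' @return the updated `"tally_state"`.
#' @export
update_tally <- function(state, call) {
  mk <- call$marker_id
  if (is.null(state[[mk]])) {
    amplisnv_stop(sprintf("unknown marker '%s' in call", mk),
                  "amplisnv_input_error")
  }
  s <- state[[mk]]
  switch(call$call_class,
    WT = { s$n_wt <- s$n_wt + 1L },
    MUT = {
      v <- call$variant
      if (is.na(v) || !v %in% names(s$n_mut)) {
        amplisnv_stop(sprintf("MUT call without a known variant for '%s'", mk),
                      "amplisnv_input_error")
      }
      s$n_mut[v] <- s$n_mut[v] + 1L
    },
    UNRECOGNIZABLE = { s$n_unrec <- s$n_unrec + 1L },
    amplisnv_stop(sprintf("unknown call class '%s'", call$call_class),
                  "amplisnv_input_error")
  )
  s$n_total <- s$n_total + 1L
  ai <- call$arrival_index
  if (!is.null(ai) && !is.na(ai)) s$last_arrival <- as.integer(ai)
  state[[mk]] <- s
  state
}

#' Build a tally from a table of locus calls
#' @param calls data.frame of locus calls (as produced by [call_reads()]).
#' @param panel the panel the calls refer to.
#' @return a `"tally_state"`.
#' @export
tally_calls <- function(calls, panel) {
  st <- new_tally(panel)
  for (mk in names(st)) {
    sub <- calls[calls$marker_id == mk, , drop = FALSE]
    if (!nrow(sub)) next
    s <- st[[mk]]
    s$n_wt <- sum(sub$call_class == "WT")
    for (v in names(s$n_mut)) {
      s$n_mut[v] <- sum(sub$call_class == "MUT" & sub$variant == v, na.rm = TRUE)
    }
    s$n_unrec <- sum(sub$call_class == "UNRECOGNIZABLE")
    s$n_total <- nrow(sub)
    s$last_arrival <- max(sub$arrival_index)
    st[[mk]] <- s
  }
  st
}

#' @export
print.tally_state <- function(x, ...) {
  cat("Per-marker tallies:\n")
  for (mk in names(x)) {
    s <- x[[mk]]
    v <- marker_vaf(x, mk)
    cat(sprintf("  %-14s total %5d | wt %5d | mut %5d (%s) | unrec %4d | VAF %s\n",
                mk, s$n_total, s$n_wt, sum(s$n_mut),
                paste(sprintf("%s:%d", names(s$n_mut), s$n_mut), collapse = ","),
                s$n_unrec,
                if (is.na(v)) "no data" else sprintf("%.3f", v)))
  }
  invisible(x)
}

#' Variant allele fraction of a marker
#'
#' The default denominator is every assigned call at the marker, including
#' unrecognizable ones — the convention under which 55 mutant calls among 85
#' assigned reads report ~65 %. The alternative estimator restricted to
#' interpretable calls, mut / (mut + wt), is available as
#' `denominator = "called"`.
#'
#' @param state a `"tally_state"`.
#' @param marker_id marker to report.
#' @param variant a variant name for a per-variant fraction, or `NULL` for
#'   all mutant calls combined.
#' @param denominator `"all"` (default) or `"called"`.
#' @return a fraction in \[0, 1\], or `NA_real_` when the marker has no
#'   assigned calls ("no data", never a division error).
#' @export
marker_vaf <- function(state, marker_id, variant = NULL,
                       denominator = c("all", "called")) {
  denominator <- match.arg(denominator)
  s <- state[[marker_id]]
  if (is.null(s)) {
    amplisnv_stop(sprintf("unknown marker '%s'", marker_id), "amplisnv_input_error")
  }
  num <- if (is.null(variant)) sum(s$n_mut) else {
    if (!variant %in% names(s$n_mut)) {
      amplisnv_stop(sprintf("unknown variant '%s' for marker '%s'", variant,
                            marker_id), "amplisnv_input_error")
    }
    s$n_mut[[variant]]
  }
  den <- if (denominator == "all") s$n_total else s$n_wt + sum(s$n_mut)
  if (den == 0L) return(NA_real_)
  num / den
}

# per-read calling core shared by the FASTQ and PAF entry points:
# given the read's accepted records grouped on one amplicon, emit one call
# per marker whose record covers the junction
calls_for_read <- function(records, panel, flank, tol, arrival_index) {
  out <- list()
  for (i in seq_len(nrow(records))) {
    rec <- records[i, , drop = FALSE]
    mk <- panel$markers[[rec$target_id]]
    if (is.null(mk)) next
    ins <- extract_locus_insertion(rec, panel$targets[[rec$target_id]],
                                   flank = flank, tol = tol)
    cl <- classify_call(ins, mk)
    if (is.null(cl)) next
    out[[length(out) + 1L]] <- data.frame(
      read_id = rec$read_id, marker_id = mk$marker_id,
      call_class = cl$call_class, variant = cl$variant,
      inserted_seq = cl$inserted_seq, arrival_index = arrival_index,
      stringsAsFactors = FALSE)
  }
  out
}

#' Call hotspot variants from reads
#'
#' The full pipeline: each read is assigned to an amplicon (k-mer
#' preselection with an exhaustive alignment fallback), aligned to the
#' modified targets of every marker on that amplicon, and classified at each
#' marker from the artificial insertion observed at the deletion junction.
#' One read yields up to one call per marker on its amplicon (the two TERT
#' promoter sites are called independently from the same read).
#'
#' @param reads named character vector of read sequences in arrival order
#'   (e.g. from [read_reads()]), or a `"sim_run"`.
#' @param panel an `"amplicon_panel"`.
#' @param params an [align_params()].
#' @param flank junction flank requirement (default: the panel's).
#' @param tol junction attribution tolerance.
#' @param prefilter use k-mer amplicon/strand preselection (alignment against
#'   all targets on both strands is used as fallback and when `FALSE`).
#' @param band dynamic-programming band: `"auto"` (half-width
#'   `max(50, 0.1 * read length)`, validated against the full dynamic
#'   program in the test suite), a number, or `0` for the exact full DP.
#' @return object of class `"amplicall"`: `calls` (per-read locus calls),
#'   `tally` (a `"tally_state"`), `n_reads`, `n_unassigned` (reads with no
#'   accepted alignment), `panel_digest` and the effective parameters.
#' @export
call_reads <- function(reads, panel, params = align_params(),
                       flank = panel$flank, tol = 2L, prefilter = TRUE,
                       band = "auto") {
  if (inherits(reads, "sim_run")) reads <- reads$reads
  n <- length(reads)
  ids <- names(reads) %||% sprintf("read_%06d", seq_len(n))
  reads <- toupper(as.character(reads))
  index <- if (prefilter) build_kmer_index(panel) else NULL
  all_targets <- panel$targets
  mk_by_amp <- lapply(names(panel$amplicons), function(a)
    names(markers_on(panel, a)))
  names(mk_by_amp) <- names(panel$amplicons)
  tg_seq <- vapply(panel$targets, `[[`, "", "sequence")
  tg_junc <- vapply(panel$targets, function(t) as.integer(t$junction), 0L)
  wt_of <- vapply(panel$markers, `[[`, "", "wt_allele")
  muts_of <- lapply(panel$markers, `[[`, "mut_alleles")

  cap <- 2L * n + 8L; k <- 0L
  c_read <- character(cap); c_mk <- character(cap); c_class <- character(cap)
  c_var <- character(cap); c_ins <- character(cap); c_ai <- integer(cap)
  fallback_calls <- list()
  n_unassigned <- 0L
  for (i in seq_len(n)) {
    read <- reads[[i]]
    hit <- if (prefilter) assign_read_kmer(read, index) else NULL
    done <- FALSE
    if (!is.null(hit)) {
      oriented <- if (hit$strand == "-") revcomp(read) else read
      b <- if (identical(band, "auto")) {
        max(50L, as.integer(0.1 * nchar(read)))
      } else as.integer(band)
      min_score <- params$min_score_frac * params$match * nchar(read)
      for (mk in mk_by_amp[[hit$amplicon_id]]) {
        a <- align_pair_cpp(oriented, tg_seq[[mk]], params$match,
                            params$mismatch, -params$gap_open,
                            -params$gap_extend, b)
        if (a$score < min_score) next
        done <- TRUE
        ins <- extract_cs_insertion_cpp(a$cs, a$tstart, a$tend, tg_junc[[mk]],
                                        flank, tol)
        if (is.na(ins)) next
        if (ins == wt_of[[mk]]) {
          cls <- "WT"; var <- NA_character_
        } else {
          hit2 <- match(ins, muts_of[[mk]])
          if (!is.na(hit2)) {
            cls <- "MUT"; var <- names(muts_of[[mk]])[hit2]
          } else {
            cls <- "UNRECOGNIZABLE"; var <- NA_character_
          }
        }
        k <- k + 1L
        c_read[k] <- ids[i]; c_mk[k] <- mk; c_class[k] <- cls
        c_var[k] <- var; c_ins[k] <- ins; c_ai[k] <- i
      }
    }
    if (!done) {  # fallback: both strands against every target, exact DP
      recs <- align_read(read, all_targets, params = params, read_id = ids[i])
      if (!nrow(recs)) {
        n_unassigned <- n_unassigned + 1L
        next
      }
      best <- best_alignment(recs)
      amp <- panel$markers[[best$target_id]]$amplicon_id
      keep <- vapply(recs$target_id, function(tid)
        panel$markers[[tid]]$amplicon_id == amp, TRUE) &
        recs$strand == best$strand
      fallback_calls <- c(fallback_calls,
                          calls_for_read(recs[keep, , drop = FALSE], panel,
                                         flank, tol, arrival_index = i))
    }
  }
  calls <- data.frame(read_id = c_read[seq_len(k)],
                      marker_id = c_mk[seq_len(k)],
                      call_class = c_class[seq_len(k)],
                      variant = c_var[seq_len(k)],
                      inserted_seq = c_ins[seq_len(k)],
                      arrival_index = c_ai[seq_len(k)],
                      stringsAsFactors = FALSE)
  if (length(fallback_calls)) {
    calls <- rbind(calls, do.call(rbind, fallback_calls))
    calls <- calls[order(calls$arrival_index), , drop = FALSE]
  }
  rownames(calls) <- NULL
  structure(list(calls = calls, tally = tally_calls(calls, panel),
                 n_reads = n, n_unassigned = n_unassigned,
                 panel_digest = panel_digest(panel),
                 params = list(align = unclass(params), flank = flank,
                               tol = tol, prefilter = prefilter,
                               band = band)),
            class = "amplicall")
}

#' Call hotspot variants from imported PAF alignments
#'
#' Uses externally produced alignments (against the panel's modified
#' targets, e.g. exported with [panel_fasta()]) instead of the internal
#' aligner. Per read, the best-scoring record picks the amplicon group and
#' strand; every marker of that amplicon with a surviving record is then
#' classified. Arrival order is the order of first appearance in the PAF.
#'
#' @param paf path to a PAF file (with cs tags) or a parsed records
#'   data.frame from [parse_paf()].
#' @param panel an `"amplicon_panel"`.
#' @param params an [align_params()] (supplies the acceptance threshold;
#'   records without a score are kept).
#' @param flank,tol as in [call_reads()].
#' @return an `"amplicall"` object.
#' @export
call_paf <- function(paf, panel, params = align_params(),
                     flank = panel$flank, tol = 2L) {
  records <- if (is.data.frame(paf)) paf else parse_paf(paf)
  known <- records$target_id %in% names(panel$targets)
  records <- records[known, , drop = FALSE]
  ok <- is.na(records$score) |
    records$score >= params$min_score_frac * params$match * records$qlen
  records <- records[ok, , drop = FALSE]
  read_order <- unique(records$read_id)
  calls <- vector("list", length(read_order))
  for (i in seq_along(read_order)) {
    recs <- records[records$read_id == read_order[i], , drop = FALSE]
    best <- best_alignment(recs)
    amp <- panel$markers[[best$target_id]]$amplicon_id
    keep <- vapply(recs$target_id, function(tid)
      panel$markers[[tid]]$amplicon_id == amp, TRUE) & recs$strand == best$strand
    calls[[i]] <- calls_for_read(recs[keep, , drop = FALSE], panel, flank, tol,
                                 arrival_index = i)
  }
  calls <- do.call(rbind, c(list(empty_calls()), unlist(calls, recursive = FALSE)))
  rownames(calls) <- NULL
  structure(list(calls = calls, tally = tally_calls(calls, panel),
                 n_reads = length(read_order), n_unassigned = 0L,
                 panel_digest = panel_digest(panel),
                 params = list(align = unclass(params), flank = flank,
                               tol = tol, prefilter = NA)),
            class = "amplicall")
}

# md5 of the canonical panel JSON, echoed in reports for auditability
panel_digest <- function(panel) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  write_panel(panel, tmp)
  unname(tools::md5sum(tmp))
}

#' @export
print.amplicall <- function(x, ...) {
  cat(sprintf("Variant calls from %d reads (%d unassigned)\n",
              x$n_reads, x$n_unassigned))
  print(x$tally)
  invisible(x)
}

#' Per-marker summary table of a call set
#'
#' @param object an `"amplicall"` object.
#' @param ... unused.
#' @return data.frame with one row per marker: totals per class and VAF.
#' @method summary amplicall
#' @export
summary.amplicall <- function(object, ...) {
  st <- object$tally
  df <- do.call(rbind, lapply(names(st), function(mk) {
    s <- st[[mk]]
    data.frame(marker_id = mk, n_total = s$n_total, n_wt = s$n_wt,
               n_mut = sum(s$n_mut), n_unrec = s$n_unrec,
               vaf = marker_vaf(st, mk), stringsAsFactors = FALSE)
  }))
  rownames(df) <- NULL
  df
}

#' Plot VAF trajectories of a call set
#'
#' One line per marker: running variant allele fraction against the
#' cumulative per-marker read count.
#'
#' @param x an `"amplicall"` object.
#' @param markers markers to draw (default: all with at least one call).
#' @param ... passed to [graphics::plot()].
#' @method plot amplicall
#' @export
plot.amplicall <- function(x, markers = NULL, ...) {
  st <- x$tally
  markers <- markers %||% names(st)[vapply(st, function(s) s$n_total > 0L, TRUE)]
  if (!length(markers)) {
    plot(0, 0, type = "n", xlab = "reads per marker", ylab = "VAF", ...)
    return(invisible(x))
  }
  series <- lapply(markers, function(mk) vaf_series(x, mk))
  xmax <- max(vapply(series, function(s) max(s$n, 0L), 0L))
  plot(NA, xlim = c(1, max(xmax, 2)), ylim = c(0, 1),
       xlab = "reads per marker", ylab = "VAF", ...)
  for (i in seq_along(series)) {
    if (nrow(series[[i]])) lines(series[[i]]$n, series[[i]]$vaf, col = i, lwd = 2)
  }
  legend("topright", legend = markers, col = seq_along(markers), lwd = 2,
         cex = 0.8, bty = "n")
  invisible(x)
}
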