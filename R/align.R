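#' Alignment scoring parameters
#'
#' Local affine-gap scoring. A gap of length L costs
#' `-(gap_open + L * gap_extend)`; with the defaults a single-base gap costs
#' 6. An alignment is accepted when its score reaches
#' `min_score_frac * match * read_length` (0.4 of the perfect score by
#' default). `band > 0` restricts the dynamic program to a diagonal band of
#' that half-width, a performance option for long reads; `band = 0` is the
#' exact full dynamic program.
#'
#' @param match match score (> 0).
#' @param mismatch mismatch penalty (<= 0).
#' @param gap_open gap opening penalty (<= 0).
#' @param gap_extend gap extension penalty (<= 0).
#' @param min_score_frac acceptance threshold as a fraction of the perfect
#'   score.
#' @param band diagonal band half-width; 0 for full dynamic programming.
#' @return object of class `"align_params"`.
#' @export
align_params <- function(match = 2L, mismatch = -4L, gap_open = -4L,
                         gap_extend = -2L, min_score_frac = 0.4, band = 0L) {
  if (match <= 0 || mismatch > 0 || gap_open > 0 || gap_extend > 0) {
    amplisnv_stop("match must be > 0; penalties must be <= 0", "amplisnv_config_error")
  }
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 min_score_frac = min_score_frac, band = as.integer(band)),
            class = "align_params")
}

empty_records <- function() {
  data.frame(read_id = character(), target_id = character(),
             strand = character(), qlen = integer(), qstart = integer(),
             qend = integer(), tlen = integer(), tstart = integer(),
             tend = integer(), score = integer(), cs = character(),
             stringsAsFactors = FALSE)
}

# one strand-resolved alignment of (possibly reoriented) query vs target;
# query coordinates are reported on the ORIGINAL read (PAF convention),
# cs and target coordinates on the forward target
align_one <- function(read, read_id, target_seq, target_id, params) {
  qlen <- nchar(read)
  fw <- align_pair_cpp(read, target_seq, params$match, params$mismatch,
                       -params$gap_open, -params$gap_extend, params$band)
  rc <- align_pair_cpp(revcomp(read), target_seq, params$match, params$mismatch,
                       -params$gap_open, -params$gap_extend, params$band)
  use_rc <- rc$score > fw$score
  a <- if (use_rc) rc else fw
  if (a$score <= 0) return(NULL)
  qs <- a$qstart; qe <- a$qend
  if (use_rc) { tmp <- qs; qs <- qlen - qe; qe <- qlen - tmp }
  data.frame(read_id = read_id, target_id = target_id,
             strand = if (use_rc) "-" else "+",
             qlen = qlen, qstart = qs, qend = qe,
             tlen = nchar(target_seq), tstart = a$tstart, tend = a$tend,
             score = a$score, cs = a$cs, stringsAsFactors = FALSE)
}

#' Align a read against modified targets
#'
#' For each target, computes the best local affine-gap alignment of the read
#' and of its reverse complement (the better strand is reported, with the
#' difference string always in forward-target orientation) and drops records
#' scoring below the acceptance threshold. Deterministic for fixed inputs.
#'
#' @param read DNA string (`N` allowed, scored as mismatch-only).
#' @param targets list of `"modified_target"` objects, or a named character
#'   vector of target sequences.
#' @param params an [align_params()].
#' @param read_id id recorded on the alignment records.
#' @return data.frame of alignment records (possibly zero rows) with columns
#'   read_id, target_id, strand, qlen, qstart, qend, tlen, tstart, tend,
#'   score, cs. Coordinates are 0-based half-open; query coordinates are on
#'   the original read.
#' @export
align_read <- function(read, targets, params = align_params(), read_id = "read") {
  read <- toupper(read)
  if (!nzchar(read)) amplisnv_stop("empty read", "amplisnv_input_error")
  if (!grepl("^[ACGTN]+$", read)) {
    amplisnv_stop("read contains characters other than A/C/G/T/N",
                  "amplisnv_input_error")
  }
  if (is.character(targets)) {
    targets <- lapply(seq_along(targets), function(i)
      list(marker_id = names(targets)[i], sequence = targets[[i]]))
  }
  if (!length(targets)) amplisnv_stop("no targets", "amplisnv_input_error")
  min_score <- params$min_score_frac * params$match * nchar(read)
  recs <- lapply(targets, function(tg)
    align_one(read, read_id, tg$sequence, tg$marker_id, params))
  recs <- recs[!vapply(recs, is.null, TRUE)]
  if (!length(recs)) return(empty_records())
  out <- do.call(rbind, recs)
  out[out$score >= min_score, , drop = FALSE]
}

#' Select the best alignment among a read's records
#'
#' Highest score wins; ties are broken by longer aligned target span, then by
#' lexicographically smallest target_id. Returns `NULL` for empty input.
#'
#' @param records alignment records (one read).
#' @return single-row data.frame, or `NULL`.
#' @export
best_alignment <- function(records) {
  if (is.null(records) || nrow(records) == 0L) return(NULL)
  if (length(unique(records$read_id)) > 1L) {
    amplisnv_stop("best_alignment requires records of a single read",
                  "amplisnv_input_error")
  }
  span <- records$tend - records$tstart
  ord <- order(-records$score, -span, records$target_id)
  records[ord[1L], , drop = FALSE]
}

# tokenize a cs difference string into ops:
#   list of (op = ":" | "*" | "+" | "-", len, seq)
parse_cs <- function(cs) {
  if (!nzchar(cs)) return(list())
  m <- gregexpr(":[0-9]+|\\*[A-Za-z]{2}|\\+[A-Za-z]+|-[A-Za-z]+", cs)[[1]]
  toks <- regmatches(cs, list(m))[[1]]
  if (sum(nchar(toks)) != nchar(cs)) {
    amplisnv_stop(sprintf("malformed cs string: %s", cs), "amplisnv_parse_error")
  }
  lapply(toks, function(tk) {
    op <- substr(tk, 1L, 1L)
    body <- toupper(substr(tk, 2L, nchar(tk)))
    list(op = op,
         len = switch(op, ":" = as.integer(body), "*" = 1L, nchar(body)),
         seq = if (op == ":") "" else body)
  })
}

# total target (reference) bases consumed by a cs string
cs_target_span <- function(ops) {
  sum(vapply(ops, function(o) switch(o$op, ":" = o$len, "*" = 1L,
                                     "-" = o$len, 0L), 0L))
}

#' Write alignment records as PAF
#'
#' Standard 12 mandatory columns plus `AS:i` (score) and `cs:Z`
#' (difference-encoding) tags.
#'
#' @param records alignment records data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_paf <- function(records, path) {
  lines <- vapply(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    ops <- parse_cs(r$cs)
    nmatch <- sum(vapply(ops, function(o) if (o$op == ":") o$len else 0L, 0L))
    alnlen <- sum(vapply(ops, function(o) o$len, 0L))
    cs_out <- gsub("([*+-][A-Z]+)", "\\L\\1", r$cs, perl = TRUE)
    paste(r$read_id, r$qlen, r$qstart, r$qend, r$strand, r$target_id,
          r$tlen, r$tstart, r$tend, nmatch, alnlen, 60,
          sprintf("AS:i:%d", r$score), sprintf("cs:Z:%s", cs_out),
          sep = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Parse PAF alignments with a cs difference tag
#'
#' Reads the 12 mandatory PAF columns plus tags; records lacking a `cs:Z`
#' tag are rejected and counted (attribute `"rejected"` on the result, with
#' one warning summarizing the count). Malformed lines raise an error naming
#' the line number. Minus-strand records keep the PAF convention: query
#' coordinates on the original read, cs in forward-target orientation.
#'
#' @param x path to a PAF file, or a character vector of PAF lines.
#' @return alignment records data.frame (columns as [align_read()]), with
#'   attribute `rejected` = number of tag-less records skipped.
#' @export
parse_paf <- function(x) {
  lines <- if (length(x) == 1L && file.exists(x)) readLines(x) else x
  lines <- lines[nzchar(lines)]
  rejected <- 0L
  rows <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 12L) {
      amplisnv_stop(sprintf("PAF line %d: fewer than 12 mandatory columns", i),
                    "amplisnv_parse_error")
    }
    nums <- suppressWarnings(as.integer(f[c(2, 3, 4, 7, 8, 9)]))
    if (any(is.na(nums)) || !f[5] %in% c("+", "-")) {
      amplisnv_stop(sprintf("PAF line %d: malformed coordinate or strand field", i),
                    "amplisnv_parse_error")
    }
    tags <- f[-(1:12)]
    cs_tag <- tags[startsWith(tags, "cs:Z:")]
    if (!length(cs_tag)) {
      rejected <- rejected + 1L
      next
    }
    cs <- toupper(sub("^cs:Z:", "", cs_tag[1L]))
    parse_cs(cs)  # validates
    as_tag <- tags[startsWith(tags, "AS:i:")]
    score <- if (length(as_tag)) as.integer(sub("^AS:i:", "", as_tag[1L])) else NA_integer_
    rows[[i]] <- data.frame(read_id = f[1], target_id = f[6], strand = f[5],
                            qlen = nums[1], qstart = nums[2], qend = nums[3],
                            tlen = nums[4], tstart = nums[5], tend = nums[6],
                            score = score, cs = cs, stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, TRUE)]
  out <- if (length(rows)) do.call(rbind, rows) else empty_records()
  if (rejected > 0L) {
    warning(sprintf("%d PAF record(s) without a cs tag were rejected", rejected))
  }
  attr(out, "rejected") <- rejected
  out
}

# --- k-mer preselection -----------------------------------------------------
# Reads are assigned to an amplicon and strand by exact k-mer votes before
# alignment, so each read is aligned only against the winning amplicon's
# modified targets. k-mers shared between amplicons (or strands) are marked
# ambiguous and never vote.

build_kmer_index <- function(panel, k = 13L) {
  env <- new.env(parent = emptyenv())
  add <- function(seq, amp_id, strand) {
    n <- nchar(seq)
    if (n < k) return()
    kmers <- substring(seq, 1:(n - k + 1L), k:n)
    for (km in unique(kmers)) {
      cur <- env[[km]]
      val <- c(amp_id, strand)
      if (is.null(cur)) env[[km]] <- val
      else if (!identical(cur, val)) env[[km]] <- NA  # ambiguous
    }
  }
  for (amp in panel$amplicons) {
    add(amp$sequence, amp$amplicon_id, "+")
    add(revcomp(amp$sequence), amp$amplicon_id, "-")
  }
  attr(env, "k") <- k
  env
}

# majority vote over probe k-mers; NULL when inconclusive
assign_read_kmer <- function(read, index, probes = 16L) {
  k <- attr(index, "k")
  n <- nchar(read)
  if (n < k) return(NULL)
  pos <- unique(round(seq(1L, n - k + 1L, length.out = probes)))
  kmers <- substring(read, pos, pos + k - 1L)
  votes <- character()
  for (km in kmers) {
    v <- index[[km]]
    if (!is.null(v) && !anyNA(v)) votes <- c(votes, paste(v, collapse = "|"))
  }
  if (length(votes) < 2L) return(NULL)
  tab <- sort(table(votes), decreasing = TRUE)
  if (length(tab) > 1L && tab[1L] == tab[2L]) return(NULL)
  parts <- strsplit(names(tab)[1L], "|", fixed = TRUE)[[1]]
  list(amplicon_id = parts[1L], strand = parts[2L])
}
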