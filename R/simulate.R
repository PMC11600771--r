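#' Per-base sequencing error model
#'
#' Independent per-position substitution, insertion and deletion
#' probabilities. The defaults (sub 0.03, ins 0.02, del 0.03, ~8 % total)
#' mimic an R9.4-class nanopore error profile and are a modeling choice, not
#' a measured flow-cell property.
#'
#' @param sub_rate substitution probability per base, in \[0, 0.5).
#' @param ins_rate probability of inserting one uniform random base after a
#'   position, in \[0, 0.5).
#' @param del_rate deletion probability per base, in \[0, 0.5).
#' @return object of class `"error_model"`.
#' @export
error_model <- function(sub_rate = 0.03, ins_rate = 0.02, del_rate = 0.03) {
  rates <- c(sub_rate, ins_rate, del_rate)
  if (any(!is.finite(rates)) || any(rates < 0) || any(rates >= 0.5)) {
    amplisnv_stop("error rates must lie in [0, 0.5)", "amplisnv_config_error")
  }
  structure(list(sub_rate = sub_rate, ins_rate = ins_rate, del_rate = del_rate),
            class = "error_model")
}

#' A sample's true allele composition
#'
#' Maps marker ids to true variant allele fractions: the probability that a
#' template molecule carries each named mutant allele; the remainder is
#' wild-type. Markers not mentioned are fully wild-type.
#'
#' @param ... named arguments `marker_id = value`, where `value` is either a
#'   single number (assigned to the marker's sole/first named mutant when
#'   resolved against a panel) or a named numeric vector of
#'   variant-name -> fraction.
#' @param .list alternative list interface.
#' @return object of class `"sample_profile"`.
#' @export
#' @examples
#' sample_profile(IDH1_R132H = 0.5, TERT_C250T = c(C250T = 0.25))
sample_profile <- function(..., .list = NULL) {
  vals <- .list %||% list(...)
  if (length(vals) && (is.null(names(vals)) || any(!nzchar(names(vals))))) {
    amplisnv_stop("sample_profile entries must be named by marker_id",
                  "amplisnv_config_error")
  }
  vals <- lapply(vals, function(v) {
    v <- unlist(v)
    if (any(v < 0) || sum(v) > 1 + 1e-12) {
      amplisnv_stop("variant fractions must be >= 0 and sum to <= 1 per marker",
                    "amplisnv_config_error")
    }
    v
  })
  structure(vals, class = "sample_profile")
}

#' Fully wild-type profile
#' @return an empty [sample_profile()].
#' @export
wt_profile <- function() sample_profile()

#' Mix two sample profiles
#'
#' Linear mixing of template fractions, as when diluting tumor gDNA with
#' wild-type gDNA: a heterozygous profile (VAF 0.5) mixed 1:1 with wild-type
#' yields VAF 0.25.
#'
#' @param a,b [sample_profile()] objects over the same panel.
#' @param ratio_a fraction of template from `a`, in \[0, 1\].
#' @return mixed `"sample_profile"`.
#' @export
mix_profiles <- function(a, b, ratio_a) {
  if (!is.numeric(ratio_a) || length(ratio_a) != 1L || ratio_a < 0 || ratio_a > 1) {
    amplisnv_stop("ratio_a must be a single number in [0, 1]", "amplisnv_config_error")
  }
  mks <- union(names(a), names(b))
  out <- lapply(mks, function(mk) {
    va <- a[[mk]]; vb <- b[[mk]]
    vars <- union(names(va) %||% character(), names(vb) %||% character())
    if (length(vars) == 0L) {  # scalar (unresolved variant name) entries
      return(ratio_a * (va %||% 0) + (1 - ratio_a) * (vb %||% 0))
    }
    setNames(vapply(vars, function(v) {
      ratio_a * (if (v %in% names(va)) va[[v]] else 0) +
        (1 - ratio_a) * (if (v %in% names(vb)) vb[[v]] else 0)
    }, 0), vars)
  })
  names(out) <- mks
  sample_profile(.list = out)
}

# resolve scalar profile entries to variant-named vectors against a panel
resolve_profile <- function(profile, panel) {
  unknown <- setdiff(names(profile), names(panel$markers))
  if (length(unknown)) {
    amplisnv_stop(sprintf("profile markers not in panel: %s",
                          paste(unknown, collapse = ", ")),
                  "amplisnv_config_error")
  }
  out <- lapply(names(profile), function(mk) {
    v <- profile[[mk]]
    if (is.null(names(v))) {
      if (length(v) != 1L) {
        amplisnv_stop(sprintf("profile for '%s' must name its variants", mk),
                      "amplisnv_config_error")
      }
      v <- setNames(v, names(panel$markers[[mk]]$mut_alleles)[1L])
    }
    bad <- setdiff(names(v), names(panel$markers[[mk]]$mut_alleles))
    if (length(bad)) {
      amplisnv_stop(sprintf("unknown variant(s) for '%s': %s", mk,
                            paste(bad, collapse = ", ")),
                    "amplisnv_config_error")
    }
    v
  })
  setNames(out, names(profile))
}

#' Simulation run configuration
#'
#' @param n_reads total reads to emit (>= 1).
#' @param weights named sampling weights per amplicon_id (default uniform);
#'   non-negative, not all zero.
#' @param strand_prob probability a read is emitted reverse-complemented.
#' @param seed integer RNG seed, or `NULL` to use the current RNG state.
#' @param error_model an [error_model()].
#' @return object of class `"run_config"`.
#' @export
run_config <- function(n_reads, weights = NULL, strand_prob = 0.5,
                       seed = NULL, error_model = ampliSNV::error_model()) {
  n_reads <- as.integer(n_reads)
  if (is.na(n_reads) || n_reads < 1L) {
    amplisnv_stop("n_reads must be >= 1", "amplisnv_config_error")
  }
  if (!is.null(weights)) {
    if (is.null(names(weights)) || any(weights < 0) || sum(weights) <= 0) {
      amplisnv_stop("weights must be named, non-negative, not all zero",
                    "amplisnv_config_error")
    }
  }
  if (strand_prob < 0 || strand_prob > 1) {
    amplisnv_stop("strand_prob must lie in [0, 1]", "amplisnv_config_error")
  }
  structure(list(n_reads = n_reads, weights = weights,
                 strand_prob = strand_prob, seed = seed,
                 error_model = error_model),
            class = "run_config")
}

#' Amplicon abundance weights
#'
#' Uniform by default; `down` names an amplicon to down-weight by `factor`,
#' a convenience preset emulating the under-amplification of GC-rich
#' amplicons (the TERT promoter amplicon in practice) in multiplex PCR.
#'
#' @param panel an `"amplicon_panel"`.
#' @param down amplicon_id to down-weight, or `NULL`.
#' @param factor multiplicative weight for the down-weighted amplicon.
#' @return named numeric weights.
#' @export
amplicon_weights <- function(panel, down = NULL, factor = 0.2) {
  w <- setNames(rep(1, length(panel$amplicons)), names(panel$amplicons))
  if (!is.null(down)) {
    if (!down %in% names(w)) {
      amplisnv_stop(sprintf("unknown amplicon '%s'", down), "amplisnv_config_error")
    }
    w[down] <- factor
  }
  w
}

# precomputed alternatives for substitution errors: row = original base
SUB_ALT <- rbind(A = c("C", "G", "T"), C = c("A", "G", "T"),
                 G = c("A", "C", "T"), T = c("A", "C", "G"))

# corrupt a character-vector sequence per the error model; returns a string
corrupt_chars <- function(v, em) {
  n <- length(v)
  out <- v
  subm <- runif(n) < em$sub_rate
  delm <- runif(n) < em$del_rate
  insm <- runif(n) < em$ins_rate
  nsub <- sum(subm)
  if (nsub) {
    out[subm] <- SUB_ALT[cbind(match(v[subm], DNA_BASES),
                               sample.int(3L, nsub, replace = TRUE))]
  }
  if (any(delm)) out[delm] <- ""
  nins <- sum(insm)
  if (nins) {
    out[insm] <- paste0(out[insm], DNA_BASES[sample.int(4L, nins, replace = TRUE)])
  }
  paste(out, collapse = "")
}

# template char vector for an amplicon with given variant assignment
# (named character: marker_id -> variant name or "WT"); cached upstream
template_chars <- function(panel, amplicon_id, assignment) {
  v <- strsplit(panel$amplicons[[amplicon_id]]$sequence, "", fixed = TRUE)[[1]]
  for (mk_id in names(assignment)) {
    var <- assignment[[mk_id]]
    if (identical(var, "WT")) next
    mk <- panel$markers[[mk_id]]
    allele <- mk$mut_alleles[[var]]
    v[(mk$offset + 1L):(mk$offset + mk$width)] <- strsplit(allele, "", fixed = TRUE)[[1]]
  }
  v
}

#' Simulate a single amplicon read
#'
#' The template is the amplicon with each named marker's bases replaced by
#' the assigned allele; it is then corrupted position-wise per the error
#' model (substitution to a uniformly random different base, insertion of a
#' uniform random base after a position, deletion of a position) and
#' reverse-complemented with probability `strand_prob`. Uses the current RNG
#' state; seed upstream for reproducibility.
#'
#' @param panel an `"amplicon_panel"`.
#' @param amplicon_id amplicon to read from.
#' @param assignment named character vector marker_id -> variant name
#'   (`"WT"` for wild-type); markers omitted default to wild-type.
#' @param error_model an [error_model()].
#' @param strand `"+"`, `"-"`, or `"random"`.
#' @param strand_prob probability of `"-"` when `strand = "random"`.
#' @return list with `sequence` and a `truth` record (amplicon_id,
#'   assignment, strand).
#' @export
simulate_read <- function(panel, amplicon_id, assignment = character(),
                          error_model = ampliSNV::error_model(),
                          strand = c("random", "+", "-"), strand_prob = 0.5) {
  strand <- match.arg(strand)
  mks <- names(markers_on(panel, amplicon_id))
  bad <- setdiff(names(assignment), mks)
  if (length(bad)) {
    amplisnv_stop(sprintf("assignment names not on amplicon '%s': %s",
                          amplicon_id, paste(bad, collapse = ", ")),
                  "amplisnv_config_error")
  }
  full <- setNames(rep("WT", length(mks)), mks)
  full[names(assignment)] <- assignment
  v <- template_chars(panel, amplicon_id, full)
  seq <- corrupt_chars(v, error_model)
  if (strand == "random") {
    strand <- if (runif(1) < strand_prob) "-" else "+"
  }
  if (strand == "-") seq <- revcomp(seq)
  list(sequence = seq,
       truth = list(amplicon_id = amplicon_id, assignment = full, strand = strand))
}

#' Simulate a multiplex amplicon sequencing run
#'
#' Emits `n_reads` reads in arrival order (the order defines the streaming
#' index): each read's amplicon is drawn by the abundance weights, each
#' marker on that amplicon independently carries mutant allele `m` with
#' probability `profile[[marker]][m]` (else wild-type), and the read is
#' corrupted per the error model.
#'
#' @param panel an `"amplicon_panel"`.
#' @param profile a [sample_profile()]; markers must exist in the panel.
#' @param run a [run_config()].
#' @return object of class `"sim_run"`: `reads` (named character vector in
#'   arrival order), `truth` (data.frame: read_id, amplicon_id, strand, one
#'   column per panel marker with the variant name, `"WT"`, or `NA` when the
#'   read's amplicon does not carry the marker), and `config`.
#' @export
simulate_run <- function(panel, profile = wt_profile(), run = run_config(100)) {
  if (length(panel$amplicons) == 0L) {
    amplisnv_stop("empty panel", "amplisnv_config_error")
  }
  profile <- resolve_profile(profile, panel)
  weights <- run$weights %||% amplicon_weights(panel)
  unknown <- setdiff(names(weights), names(panel$amplicons))
  if (length(unknown)) {
    amplisnv_stop(sprintf("weights name unknown amplicons: %s",
                          paste(unknown, collapse = ", ")),
                  "amplisnv_config_error")
  }
  if (sum(weights) <= 0) {
    amplisnv_stop("all-zero amplicon weights", "amplisnv_config_error")
  }
  with_preserved_seed(run$seed, {
    n <- run$n_reads
    amp_ids <- sample(names(weights), n, replace = TRUE, prob = weights)
    mk_all <- names(panel$markers)
    truth_mk <- matrix(NA_character_, nrow = n, ncol = length(mk_all),
                       dimnames = list(NULL, mk_all))
    reads <- character(n)
    strands <- character(n)
    # cache template char vectors per amplicon/assignment combination
    tmpl_cache <- new.env(parent = emptyenv())
    for (i in seq_len(n)) {
      amp <- amp_ids[i]
      mks <- names(markers_on(panel, amp))
      assign_i <- setNames(rep("WT", length(mks)), mks)
      for (mk in mks) {
        fr <- profile[[mk]]
        if (is.null(fr) || length(fr) == 0L) next
        u <- runif(1)
        cum <- cumsum(fr)
        hit <- which(u < cum)
        if (length(hit)) assign_i[mk] <- names(fr)[hit[1L]]
      }
      key <- paste(amp, paste(assign_i, collapse = ","), sep = "|")
      v <- tmpl_cache[[key]]
      if (is.null(v)) {
        v <- template_chars(panel, amp, assign_i)
        tmpl_cache[[key]] <- v
      }
      seq <- corrupt_chars(v, run$error_model)
      st <- if (runif(1) < run$strand_prob) "-" else "+"
      if (st == "-") seq <- revcomp(seq)
      reads[i] <- seq
      strands[i] <- st
      truth_mk[i, mks] <- assign_i
    }
    read_ids <- sprintf("read_%06d", seq_len(n))
    truth <- data.frame(read_id = read_ids, amplicon_id = amp_ids,
                        strand = strands, stringsAsFactors = FALSE)
    truth <- cbind(truth, as.data.frame(truth_mk, stringsAsFactors = FALSE))
    structure(list(reads = setNames(reads, read_ids), truth = truth,
                   config = list(n_reads = n, weights = as.list(weights),
                                 strand_prob = run$strand_prob,
                                 seed = run$seed,
                                 error_model = unclass(run$error_model),
                                 profile = lapply(profile, as.list))),
              class = "sim_run")
  })
}

#' @export
print.sim_run <- function(x, ...) {
  cat(sprintf("Simulated run: %d reads over %d amplicon(s)\n",
              length(x$reads), length(unique(x$truth$amplicon_id))))
  print(table(x$truth$amplicon_id))
  invisible(x)
}

#' True mutant fraction per marker of a simulated run
#'
#' Computed from the truth table: among reads whose amplicon carries the
#' marker, the fraction assigned each named variant.
#'
#' @param run a `"sim_run"`.
#' @param marker_id marker to summarize.
#' @return named numeric: fraction per variant plus `"WT"`.
#' @export
truth_fraction <- function(run, marker_id) {
  col <- run$truth[[marker_id]]
  if (is.null(col)) {
    amplisnv_stop(sprintf("marker '%s' not in truth table", marker_id),
                  "amplisnv_config_error")
  }
  col <- col[!is.na(col)]
  if (!length(col)) return(setNames(numeric(), character()))
  table(col) / length(col)
}

#' Write a simulated run to disk
#'
#' Writes arrival-ordered FASTQ (uniform placeholder qualities), a truth TSV
#' and a JSON run manifest.
#'
#' @param run a `"sim_run"`.
#' @param dir output directory (created if needed).
#' @param prefix file name prefix.
#' @return named list of the three file paths, invisibly.
#' @export
write_run <- function(run, dir, prefix = "sim") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fq <- file.path(dir, paste0(prefix, ".fastq"))
  tr <- file.path(dir, paste0(prefix, "_truth.tsv"))
  mf <- file.path(dir, paste0(prefix, "_manifest.json"))
  write_fastq(run$reads, fq)
  write.table(run$truth, tr, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(run$config, mf, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(list(fastq = fq, truth = tr, manifest = mf))
}

#' Write reads as FASTQ with placeholder qualities
#' @param reads named character vector of DNA sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  dna <- Biostrings::DNAStringSet(reads)
  qual <- Biostrings::BStringSet(vapply(nchar(reads), function(w)
    strrep("I", w), ""))
  Biostrings::writeXStringSet(dna, path, format = "fastq", qualities = qual)
  invisible(path)
}

#' Read sequences from FASTQ or FASTA
#'
#' Record order is preserved (it defines the arrival order in streaming
#' analyses); qualities are ignored.
#'
#' @param path input path; format inferred from the extension
#'   (`.fastq`/`.fq` vs anything else as FASTA) unless given.
#' @param format `"auto"`, `"fastq"` or `"fasta"`.
#' @return named character vector of uppercase sequences.
#' @export
read_reads <- function(path, format = c("auto", "fastq", "fasta")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(fastq|fq)$", path, ignore.case = TRUE)) "fastq" else "fasta"
  }
  x <- Biostrings::readDNAStringSet(path, format = format)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}
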