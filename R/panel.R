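#' Define an amplicon reference
#'
#' An amplicon is one PCR product of the panel, given on the strand the panel
#' author chose; all marker coordinates are 0-based offsets on this strand.
#'
#' @param amplicon_id short unique name.
#' @param sequence uppercase DNA string (`A`/`C`/`G`/`T` only), length >= 100.
#' @param description free text.
#' @return an object of class `"amplicon"`.
#' @export
amplicon <- function(amplicon_id, sequence, description = "") {
  sequence <- toupper(sequence)
  if (!is.character(amplicon_id) || length(amplicon_id) != 1L || !nzchar(amplicon_id)) {
    amplisnv_stop("amplicon_id must be a non-empty string", "amplisnv_schema_error")
  }
  if (!is_dna(sequence)) {
    amplisnv_stop(sprintf("amplicon '%s': sequence must contain only A/C/G/T", amplicon_id),
                  "amplisnv_schema_error")
  }
  if (nchar(sequence) < 100L) {
    amplisnv_stop(sprintf("amplicon '%s': sequence shorter than 100 bases", amplicon_id),
                  "amplisnv_schema_error")
  }
  structure(list(amplicon_id = amplicon_id, sequence = sequence,
                 description = description),
            class = "amplicon")
}

#' Define a hotspot marker site
#'
#' One SNV locus on one amplicon. `offset` addresses the first base that is
#' deleted from the modified reference; `width` bases starting there are the
#' alleles compared at the deletion junction.
#'
#' @param marker_id short unique name, e.g. `"IDH1_R132"`.
#' @param amplicon_id id of the amplicon carrying the site.
#' @param offset 0-based position of the first deleted base.
#' @param width number of deleted bases (k >= 1, default 1 for a single SNV).
#' @param wt_allele wild-type allele, DNA string of length `width`.
#' @param mut_alleles named character vector / list of variant-name -> allele
#'   string (each of length `width`, each distinct from `wt_allele` and from
#'   one another); at least one entry.
#' @return an object of class `"marker_site"`.
#' @export
marker_site <- function(marker_id, amplicon_id, offset, width = 1L,
                        wt_allele, mut_alleles) {
  mut_alleles <- vapply(mut_alleles, function(x) toupper(as.character(x)), "")
  wt_allele <- toupper(wt_allele)
  if (is.null(names(mut_alleles)) || any(!nzchar(names(mut_alleles)))) {
    amplisnv_stop(sprintf("marker '%s': mut_alleles must be named", marker_id),
                  "amplisnv_schema_error")
  }
  width <- as.integer(width)
  offset <- as.integer(offset)
  if (width < 1L || offset < 0L) {
    amplisnv_stop(sprintf("marker '%s': offset must be >= 0 and width >= 1", marker_id),
                  "amplisnv_schema_error")
  }
  alleles <- c(wt_allele, unname(mut_alleles))
  if (any(nchar(alleles) != width) || !all(is_dna(alleles))) {
    amplisnv_stop(sprintf("marker '%s': alleles must be DNA strings of length %d",
                          marker_id, width), "amplisnv_schema_error")
  }
  if (anyDuplicated(alleles)) {
    amplisnv_stop(sprintf("marker '%s': alleles must be mutually distinct", marker_id),
                  "amplisnv_schema_error")
  }
  structure(list(marker_id = marker_id, amplicon_id = amplicon_id,
                 offset = offset, width = width, wt_allele = wt_allele,
                 mut_alleles = mut_alleles),
            class = "marker_site")
}

#' Delete the marker bases from a sequence
#'
#' String-level primitive behind modified targets: removes
#' `[offset, offset + width)` (0-based, half-open) from `sequence` and records
#' the junction, the position in the shortened sequence where the deletion
#' occurred.
#'
#' @param sequence DNA string.
#' @param offset 0-based position of the first deleted base.
#' @param width number of bases to delete.
#' @return list with elements `sequence` and `junction` (= `offset`).
#' @export
#' @examples
#' modified_target("ACGTACGT", 3, 1)$sequence  # "ACGACGT"
modified_target <- function(sequence, offset, width = 1L) {
  n <- nchar(sequence)
  offset <- as.integer(offset); width <- as.integer(width)
  if (offset < 0L || width < 1L || offset + width > n) {
    amplisnv_stop("deletion window out of range", "amplisnv_range_error")
  }
  list(sequence = paste0(substr(sequence, 1L, offset),
                         substr(sequence, offset + width + 1L, n)),
       junction = offset)
}

#' Build the modified reference target for a marker
#'
#' The modified target is the amplicon with the marker's bases deleted, so a
#' spanning read reports its allele as an artificial insertion at the
#' junction. Re-inserting the wild-type allele at the junction reproduces the
#' amplicon exactly.
#'
#' @param amplicon an [amplicon()] object.
#' @param marker a [marker_site()] on that amplicon.
#' @return object of class `"modified_target"` with fields `marker_id`,
#'   `sequence`, `junction`, `source_amplicon_id`, `width`.
#' @export
build_modified_target <- function(amplicon, marker) {
  if (marker$amplicon_id != amplicon$amplicon_id) {
    amplisnv_stop(sprintf("marker '%s' does not reference amplicon '%s'",
                          marker$marker_id, amplicon$amplicon_id),
                  "amplisnv_schema_error")
  }
  observed <- substr(amplicon$sequence, marker$offset + 1L,
                     marker$offset + marker$width)
  if (observed != marker$wt_allele) {
    amplisnv_stop(sprintf(
      "marker '%s': wt_allele '%s' does not match amplicon bases '%s' at offset %d",
      marker$marker_id, marker$wt_allele, observed, marker$offset),
      "amplisnv_allele_mismatch")
  }
  mt <- modified_target(amplicon$sequence, marker$offset, marker$width)
  structure(list(marker_id = marker$marker_id, sequence = mt$sequence,
                 junction = mt$junction,
                 source_amplicon_id = amplicon$amplicon_id,
                 width = marker$width),
            class = "modified_target")
}

#' Expected alleles of a marker
#'
#' The classification dictionary used at the deletion junction: the wild-type
#' allele and the named mutant alleles, all of the marker's width.
#'
#' @param marker a [marker_site()].
#' @return list with `wt` (string) and `muts` (named character vector).
#' @export
expected_alleles <- function(marker) {
  list(wt = marker$wt_allele, muts = marker$mut_alleles)
}

#' Assemble and validate a marker panel
#'
#' @param amplicons list of [amplicon()] objects.
#' @param markers list of [marker_site()] objects.
#' @param k_default default deletion width for new markers (informational).
#' @param flank minimum aligned reference bases required on each side of the
#'   junction for a read to be callable at a marker (default 10).
#' @return object of class `"amplicon_panel"` with precomputed modified
#'   targets (one per marker).
#' @export
panel <- function(amplicons, markers, k_default = 1L, flank = 10L) {
  amp_ids <- vapply(amplicons, `[[`, "", "amplicon_id")
  if (anyDuplicated(amp_ids)) {
    amplisnv_stop("duplicate amplicon_id in panel", "amplisnv_duplicate_id")
  }
  mk_ids <- vapply(markers, `[[`, "", "marker_id")
  if (anyDuplicated(mk_ids)) {
    amplisnv_stop(sprintf("duplicate marker_id: %s",
                          paste(unique(mk_ids[duplicated(mk_ids)]), collapse = ", ")),
                  "amplisnv_duplicate_id")
  }
  names(amplicons) <- amp_ids
  names(markers) <- mk_ids
  targets <- vector("list", length(markers))
  for (i in seq_along(markers)) {
    mk <- markers[[i]]
    if (!mk$amplicon_id %in% amp_ids) {
      amplisnv_stop(sprintf("marker '%s' references unknown amplicon '%s'",
                            mk$marker_id, mk$amplicon_id),
                    "amplisnv_schema_error")
    }
    amp <- amplicons[[mk$amplicon_id]]
    if (mk$offset + mk$width > nchar(amp$sequence)) {
      amplisnv_stop(sprintf("marker '%s': site outside amplicon", mk$marker_id),
                    "amplisnv_range_error")
    }
    targets[[i]] <- build_modified_target(amp, mk)  # validates wt_allele
  }
  names(targets) <- mk_ids
  structure(list(amplicons = amplicons, markers = markers, targets = targets,
                 k_default = as.integer(k_default), flank = as.integer(flank)),
            class = "amplicon_panel")
}

#' @export
print.amplicon_panel <- function(x, ...) {
  cat(sprintf("Amplicon panel: %d amplicons, %d marker sites (flank = %d)\n",
              length(x$amplicons), length(x$markers), x$flank))
  for (mk in x$markers) {
    cat(sprintf("  %-14s on %-9s offset %4d  wt %s -> {%s}\n",
                mk$marker_id, mk$amplicon_id, mk$offset, mk$wt_allele,
                paste(sprintf("%s:%s", names(mk$mut_alleles), mk$mut_alleles),
                      collapse = ", ")))
  }
  invisible(x)
}

#' Markers located on one amplicon
#' @param panel an `"amplicon_panel"`.
#' @param amplicon_id amplicon name.
#' @return list of marker_site objects (possibly several, e.g. the two TERT
#'   promoter sites share one amplicon).
#' @export
markers_on <- function(panel, amplicon_id) {
  Filter(function(mk) mk$amplicon_id == amplicon_id, panel$markers)
}

#' Read a panel configuration from JSON
#'
#' The JSON schema has top-level keys `amplicons` (objects with `id`,
#' `sequence`, `description`), `markers` (objects with `marker_id`,
#' `amplicon_id`, `offset`, `width`, `wt_allele`, `mut_alleles` map), and
#' optional `k_default` and `flank`.
#'
#' @param path file path.
#' @return validated `"amplicon_panel"`.
#' @export
load_panel <- function(path) {
  if (!file.exists(path)) {
    amplisnv_stop(sprintf("panel file not found: %s", path), "amplisnv_io_error")
  }
  raw <- tryCatch(jsonlite::read_json(path),
                  error = function(e) amplisnv_stop(
                    sprintf("panel file is not valid JSON: %s", conditionMessage(e)),
                    "amplisnv_schema_error"))
  if (!is.list(raw) || is.null(raw$amplicons) || is.null(raw$markers)) {
    amplisnv_stop("panel JSON must have 'amplicons' and 'markers' keys",
                  "amplisnv_schema_error")
  }
  amps <- lapply(raw$amplicons, function(a) {
    if (is.null(a$id) || is.null(a$sequence)) {
      amplisnv_stop("each amplicon needs 'id' and 'sequence'", "amplisnv_schema_error")
    }
    amplicon(a$id, a$sequence, a$description %||% "")
  })
  mks <- lapply(raw$markers, function(m) {
    need <- c("marker_id", "amplicon_id", "offset", "wt_allele", "mut_alleles")
    if (any(vapply(need, function(k) is.null(m[[k]]), TRUE))) {
      amplisnv_stop(sprintf("marker entry missing one of: %s",
                            paste(need, collapse = ", ")),
                    "amplisnv_schema_error")
    }
    marker_site(m$marker_id, m$amplicon_id, m$offset,
                m$width %||% (raw$k_default %||% 1L),
                m$wt_allele, unlist(m$mut_alleles))
  })
  panel(amps, mks, k_default = raw$k_default %||% 1L, flank = raw$flank %||% 10L)
}

#' Write a panel configuration to JSON
#' @param panel an `"amplicon_panel"`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  obj <- list(
    amplicons = lapply(unname(panel$amplicons), function(a)
      list(id = a$amplicon_id, sequence = a$sequence, description = a$description)),
    markers = lapply(unname(panel$markers), function(m)
      list(marker_id = m$marker_id, amplicon_id = m$amplicon_id,
           offset = m$offset, width = m$width, wt_allele = m$wt_allele,
           mut_alleles = as.list(m$mut_alleles))),
    k_default = panel$k_default,
    flank = panel$flank
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Export panel sequences as FASTA
#'
#' @param panel an `"amplicon_panel"`.
#' @param path output FASTA path.
#' @param what `"amplicons"` for the unmodified amplicons, `"modified"` for
#'   the per-marker modified targets (record ids `<marker_id>|modified`).
#' @return `path`, invisibly.
#' @export
panel_fasta <- function(panel, path, what = c("amplicons", "modified")) {
  what <- match.arg(what)
  seqs <- if (what == "amplicons") {
    setNames(vapply(panel$amplicons, `[[`, "", "sequence"),
             vapply(panel$amplicons, `[[`, "", "amplicon_id"))
  } else {
    setNames(vapply(panel$targets, `[[`, "", "sequence"),
             paste0(vapply(panel$targets, `[[`, "", "marker_id"), "|modified"))
  }
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' The built-in CNS tumor hotspot panel (synthetic amplicons)
#'
#' Eight marker sites across six amplicons covering the WHO-2021-relevant CNS
#' tumor SNV hotspots: IDH1 R132, IDH2 R172, the two TERT promoter sites C228
#' and C250 (one shared amplicon), H3F3A K27 and G34 (one shared amplicon),
#' HIST1H3B K27, and BRAF V600. Amplicon sequences are deterministic
#' *synthetic placeholders* (seeded pseudo-random DNA of realistic length,
#' 489-680 bp, the TERT amplicon GC-rich) carrying the canonical wild-type
#' base at each hotspot; they are not the genomic amplicon sequences, so the
#' panel is suitable for simulation and method validation, not for calling
#' real reads.
#'
#' @return an `"amplicon_panel"` with 6 amplicons and 8 marker sites.
#' @export
cns_panel <- function() {
  spec <- list(
    list(id = "IDH1",     len = 489L, gc = 0.50,
         markers = list(list("IDH1_R132H",  244L, "G", c(R132H = "A")))),
    list(id = "IDH2",     len = 520L, gc = 0.50,
         markers = list(list("IDH2_R172K",  260L, "G", c(R172K = "A")))),
    list(id = "TERT",     len = 560L, gc = 0.78,
         markers = list(list("TERT_C228T",  260L, "C", c(C228T = "T")),
                        list("TERT_C250T",  282L, "C", c(C250T = "T")))),
    list(id = "H3F3A",    len = 600L, gc = 0.50,
         markers = list(list("H3F3A_K27M",  290L, "A", c(K27M = "T")),
                        list("H3F3A_G34R",  311L, "G", c(G34R = "A")))),
    list(id = "HIST1H3B", len = 640L, gc = 0.50,
         markers = list(list("HIST1H3B_K27M", 310L, "A", c(K27M = "T")))),
    list(id = "BRAF",     len = 680L, gc = 0.50,
         markers = list(list("BRAF_V600E",  330L, "T", c(V600E = "A"))))
  )
  with_preserved_seed(83951, {
    amps <- list(); mks <- list()
    for (a in spec) {
      p_gc <- a$gc
      bases <- sample(DNA_BASES, a$len, replace = TRUE,
                      prob = c((1 - p_gc) / 2, p_gc / 2, p_gc / 2, (1 - p_gc) / 2))
      for (m in a$markers) {
        off <- m[[2]]; wt <- m[[3]]; muts <- m[[4]]
        bases[off + 1L] <- wt
        # keep the +/-2 junction context free of both alleles so the
        # artificial insertion cannot slide within a homopolymer run
        ctx <- setdiff(DNA_BASES, c(wt, muts))
        for (d in c(-2L, -1L, 1L, 2L)) {
          bases[off + 1L + d] <- sample(ctx, 1L)
        }
        mks[[length(mks) + 1L]] <- marker_site(m[[1]], a$id, off, 1L, wt, muts)
      }
      amps[[length(amps) + 1L]] <- amplicon(
        a$id, paste(bases, collapse = ""),
        sprintf("synthetic placeholder amplicon for %s hotspot region", a$id))
    }
    panel(amps, mks)
  })
}
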