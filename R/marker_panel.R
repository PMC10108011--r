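#' Locate CpG dinucleotides in a DNA sequence
#'
#' Returns the 0-based offsets `p` such that `substr(seq, p + 1, p + 2)` is
#' exactly `"CG"`. These are the positions interrogated by the methylation
#' readout: after bisulfite conversion a methylated CpG is read as CG and an
#' unmethylated CpG as TG.
#'
#' @param seq A single DNA string over A/C/G/T.
#' @return Integer vector of 0-based offsets, ascending (possibly empty).
#' @examples
#' find_cpg_sites("ACGT")  # 1
#' find_cpg_sites("CGCG")  # 0 2
#' @export
find_cpg_sites <- function(seq) {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq))
    input_error("'seq' must be a single DNA string")
  if (grepl("[^ACGT]", seq))
    input_error("'seq' contains characters outside A/C/G/T")
  m <- gregexpr("(?=CG)", seq, perl = TRUE)[[1]]
  if (m[1] == -1L) return(integer(0))
  as.integer(m) - 1L
}

#' Construct a single amplicon marker definition
#'
#' A marker is one amplicon target: its unconverted reference sequence in
#' sequencing orientation, the CpG map, the primer footprints and the
#' demultiplexing barcode. All coordinates are 0-based, half-open.
#'
#' @param name Marker identifier.
#' @param reference_seq Unconverted reference sequence (A/C/G/T), amplicon
#'   orientation, length >= 40.
#' @param cpg_positions Integer vector of 0-based CpG offsets; every offset
#'   must sit on a CG dinucleotide, strictly increasing, and outside both
#'   primer spans.
#' @param primer_fwd,primer_rev Length-2 integer vectors `c(start, end)`
#'   (0-based, half-open) giving the primer footprints within
#'   `reference_seq`. Each primer must contain at least four cytosines not
#'   followed by G (CH sites), the design rule that makes amplification
#'   specific to bisulfite-converted molecules.
#' @param barcode Short DNA tag prepended to reads from this marker.
#' @return A `marker_definition` object.
#' @export
marker_definition <- function(name, reference_seq, cpg_positions,
                              primer_fwd, primer_rev, barcode) {
  m <- structure(
    list(name = as.character(name),
         reference_seq = toupper(as.character(reference_seq)),
         cpg_positions = as.integer(cpg_positions),
         primer_fwd = as.integer(primer_fwd),
         primer_rev = as.integer(primer_rev),
         barcode = toupper(as.character(barcode))),
    class = "marker_definition")
  validate_marker(m)
  m
}

# Count cytosines in a span that are NOT followed by G (CH sites).
.count_ch <- function(seq, span) {
  s <- substr(seq, span[1] + 1L, span[2])
  # a C at the span's right edge is judged against the full sequence context
  chars <- strsplit(seq, "")[[1]]
  idx <- seq.int(span[1] + 1L, span[2])
  sum(vapply(idx, function(i) {
    chars[i] == "C" && (i == length(chars) || chars[i + 1L] != "G")
  }, logical(1)))
}

#' Validate a marker definition
#'
#' Checks the invariants of the amplicon design: CpG offsets sit on CG,
#' are strictly increasing and outside primers; each primer carries >= 4 CH
#' cytosines; the reference is >= 40 bp with >= 1 CpG outside primers.
#'
#' @param m A `marker_definition`.
#' @return `m`, invisibly, if valid; otherwise a validation error naming the
#'   marker and the violated rule.
#' @export
validate_marker <- function(m) {
  nm <- m$name
  seq <- m$reference_seq
  if (is.na(nm) || !nzchar(nm))
    validation_error("marker has an empty name")
  if (grepl("[^ACGT]", seq))
    validation_error(sprintf("marker '%s': reference_seq has non-ACGT characters", nm))
  if (nchar(seq) < 40L)
    validation_error(sprintf("marker '%s': reference_seq shorter than 40 bp", nm))
  for (p in m$cpg_positions) {
    if (p < 0L || p + 2L > nchar(seq) || substr(seq, p + 1L, p + 2L) != "CG")
      validation_error(sprintf(
        "marker '%s': cpg_position %d is not on a CG dinucleotide", nm, p))
  }
  if (length(m$cpg_positions) > 1L && any(diff(m$cpg_positions) <= 0L))
    validation_error(sprintf("marker '%s': cpg_positions not strictly increasing", nm))
  for (span in list(fwd = m$primer_fwd, rev = m$primer_rev)) {
    if (length(span) != 2L || span[1] < 0L || span[2] > nchar(seq) || span[1] >= span[2])
      validation_error(sprintf("marker '%s': malformed primer span", nm))
  }
  in_span <- function(p, span) p >= span[1] & p < span[2]
  if (any(in_span(m$cpg_positions, m$primer_fwd) |
          in_span(m$cpg_positions, m$primer_rev)))
    validation_error(sprintf("marker '%s': cpg_position inside a primer span", nm))
  if (.count_ch(seq, m$primer_fwd) < 4L)
    validation_error(sprintf(
      "marker '%s': forward primer has fewer than 4 CH cytosines", nm))
  if (.count_ch(seq, m$primer_rev) < 4L)
    validation_error(sprintf(
      "marker '%s': reverse primer has fewer than 4 CH cytosines", nm))
  if (length(m$cpg_positions) < 1L)
    validation_error(sprintf("marker '%s': no CpG outside primers", nm))
  if (grepl("[^ACGT]", m$barcode) || !nzchar(m$barcode))
    validation_error(sprintf("marker '%s': barcode must be non-empty A/C/G/T", nm))
  invisible(m)
}

#' Construct a marker panel
#'
#' @param markers List of `marker_definition` objects. Names and barcodes
#'   must be unique across the panel.
#' @param version Free-text version tag.
#' @return A `marker_panel` object.
#' @export
marker_panel <- function(markers, version = "1") {
  if (!length(markers)) validation_error("panel has no markers")
  lapply(markers, validate_marker)
  nms <- vapply(markers, `[[`, character(1), "name")
  bcs <- vapply(markers, `[[`, character(1), "barcode")
  if (anyDuplicated(nms))
    validation_error(sprintf("duplicate marker name: %s", nms[duplicated(nms)][1]))
  if (anyDuplicated(bcs))
    validation_error(sprintf("duplicate barcode: %s", bcs[duplicated(bcs)][1]))
  names(markers) <- nms
  structure(list(markers = markers, version = as.character(version)),
            class = "marker_panel")
}

#' @export
print.marker_panel <- function(x, ...) {
  cat(sprintf("marker_panel (version %s) with %d markers\n",
              x$version, length(x$markers)))
  for (m in x$markers)
    cat(sprintf("  %-12s %3d bp, %d CpGs, barcode %s\n",
                m$name, nchar(m$reference_seq), length(m$cpg_positions),
                m$barcode))
  invisible(x)
}

#' @export
length.marker_panel <- function(x) length(x$markers)

#' In-silico bisulfite conversion of a marker reference
#'
#' Bisulfite treatment converts unmethylated cytosines to uracil (read as T)
#' while methylated cytosines stay C. Non-CpG cytosines (CH sites) are taken
#' as never methylated and always convert. CpG cytosines convert only when
#' the molecule is unmethylated.
#'
#' @param marker A `marker_definition`.
#' @param cpg_methylated If `TRUE`, cytosines at `cpg_positions` are kept as
#'   C (methylated template); if `FALSE` they convert to T (unmethylated
#'   template).
#' @return The converted sequence, same length as the reference.
#' @export
bisulfite_convert_reference <- function(marker, cpg_methylated = FALSE) {
  validate_marker(marker)
  bisulfite_convert_seq(marker$reference_seq, marker$cpg_positions,
                        cpg_methylated)
}

# seq-level workhorse, also used by the read simulator
bisulfite_convert_seq <- function(seq, cpg_positions, cpg_methylated) {
  chars <- strsplit(seq, "")[[1]]
  is_c <- chars == "C"
  keep <- rep(FALSE, length(chars))
  if (cpg_methylated && length(cpg_positions))
    keep[cpg_positions + 1L] <- TRUE
  chars[is_c & !keep] <- "T"
  paste(chars, collapse = "")
}

# ---- panel file I/O ---------------------------------------------------------
# TSV, one row per marker: name, barcode, reference_seq,
# cpg_positions (comma-joined, 0-based), primer_fwd "start-end",
# primer_rev "start-end" (half-open). A leading '#' line carries the version.

.parse_span <- function(s, what, line) {
  parts <- strsplit(s, "-", fixed = TRUE)[[1]]
  if (length(parts) != 2L || anyNA(suppressWarnings(as.integer(parts))))
    format_error(sprintf("line %d: cannot parse %s span '%s'", line, what, s))
  as.integer(parts)
}

#' Read a marker panel from a TSV file
#'
#' Expected columns: `name`, `barcode`, `reference_seq`, `cpg_positions`
#' (comma-joined 0-based offsets), `primer_fwd` and `primer_rev` as
#' `start-end` (0-based half-open). An optional first line
#' `# panel_version: <tag>` sets the version.
#'
#' @param path Path to the panel file.
#' @return A validated `marker_panel`.
#' @export
load_panel <- function(path) {
  if (!file.exists(path)) input_error(sprintf("panel file not found: %s", path))
  lines <- readLines(path)
  version <- "1"
  if (length(lines) && grepl("^#\\s*panel_version:", lines[1])) {
    version <- trimws(sub("^#\\s*panel_version:", "", lines[1]))
    lines <- lines[-1]
  }
  tab <- tryCatch(
    utils::read.delim(text = lines, stringsAsFactors = FALSE,
                      colClasses = "character"),
    error = function(e) format_error(sprintf("panel parse failure: %s",
                                             conditionMessage(e))))
  need <- c("name", "barcode", "reference_seq", "cpg_positions",
            "primer_fwd", "primer_rev")
  missing <- setdiff(need, names(tab))
  if (length(missing))
    format_error(sprintf("panel file missing column(s): %s",
                         paste(missing, collapse = ", ")))
  markers <- lapply(seq_len(nrow(tab)), function(i) {
    row <- tab[i, ]
    line <- i + 1L  # header is line 1
    cpg <- if (nzchar(trimws(row$cpg_positions)))
      suppressWarnings(as.integer(strsplit(row$cpg_positions, ",")[[1]]))
    else integer(0)
    if (anyNA(cpg))
      format_error(sprintf("line %d: cannot parse cpg_positions '%s'",
                           line, row$cpg_positions))
    marker_definition(row$name, row$reference_seq, cpg,
                      .parse_span(row$primer_fwd, "primer_fwd", line),
                      .parse_span(row$primer_rev, "primer_rev", line),
                      row$barcode)
  })
  marker_panel(markers, version = version)
}

#' Write a marker panel to a TSV file
#'
#' Inverse of [load_panel()]: writing then loading reproduces the panel.
#'
#' @param panel A `marker_panel`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "marker_panel"))
  rows <- vapply(panel$markers, function(m) {
    paste(m$name, m$barcode, m$reference_seq,
          paste(m$cpg_positions, collapse = ","),
          paste(m$primer_fwd, collapse = "-"),
          paste(m$primer_rev, collapse = "-"),
          sep = "\t")
  }, character(1))
  writeLines(c(sprintf("# panel_version: %s", panel$version),
               paste("name", "barcode", "reference_seq", "cpg_positions",
                     "primer_fwd", "primer_rev", sep = "\t"),
               rows), path)
  invisible(path)
}

#' Export panel references as FASTA
#'
#' Writes the unconverted references, or their in-silico bisulfite-converted
#' templates, for inspection with standard sequence tools.
#'
#' @param panel A `marker_panel`.
#' @param path Output FASTA path.
#' @param converted One of `"none"` (unconverted reference),
#'   `"methylated"` (CpGs kept as C) or `"unmethylated"` (all C to T).
#' @return `path`, invisibly.
#' @export
panel_to_fasta <- function(panel, path,
                           converted = c("none", "methylated", "unmethylated")) {
  converted <- match.arg(converted)
  seqs <- vapply(panel$markers, function(m) {
    switch(converted,
           none = m$reference_seq,
           methylated = bisulfite_convert_reference(m, TRUE),
           unmethylated = bisulfite_convert_reference(m, FALSE))
  }, character(1))
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- names(panel$markers)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

# ---- fixture panel ----------------------------------------------------------

# Deterministic synthetic amplicon builder. Sequences use only spacer blocks
# with no G outside explicit CG units, so every CG in the final sequence is a
# designed CpG and the CpG map equals find_cpg_sites() of the reference.
.build_amplicon <- function(n_cpg, idx) {
  fwd_variants <- c("ACTTACTTACTTACTTACTT", "TCTATCTATCTATCTATCTA",
                    "CATTCATTCATTCATTCATT", "TTCATTCATTCATTCATTCA")
  rev_variants <- c("TCAATCAATCAATCAATCAA", "ATCTATCTATCTATCTATCT",
                    "AACTAACTAACTAACTAACT", "CTTACTTACTTACTTACTTA")
  spacers <- c("ATTA", "TACT", "TTAT", "AATC", "TCTA")
  fwd <- fwd_variants[(idx - 1L) %% length(fwd_variants) + 1L]
  rev <- rev_variants[(idx - 1L) %% length(rev_variants) + 1L]
  mid <- character(0)
  for (j in seq_len(n_cpg)) {
    mid <- c(mid, spacers[(idx + j - 1L) %% length(spacers) + 1L], "CG")
  }
  mid <- c(mid, spacers[(idx) %% length(spacers) + 1L])
  seq <- paste0(fwd, paste(mid, collapse = ""), rev)
  list(seq = seq,
       primer_fwd = c(0L, nchar(fwd)),
       primer_rev = c(nchar(seq) - nchar(rev), nchar(seq)))
}

#' The default 8-marker colorectal panel (synthetic sequences)
#'
#' Eight colon-specific markers are used for the c-cfDNA readout: FGFRL1,
#' Col1, ECH1, cg10900049, cg23460250, cg12462916, cg09094964 and
#' cg15139063. The true amplicon sequences of the assay are not public, so
#' this fixture carries those marker names on deterministic synthetic
#' amplicons (4-8 CpGs each, >= 4 CH cytosines per primer); it exercises the
#' full pipeline without claiming anything about the real loci.
#'
#' @return A `marker_panel` with 8 markers.
#' @export
default_panel <- function() {
  names8 <- c("FGFRL1", "Col1", "ECH1", "cg10900049", "cg23460250",
              "cg12462916", "cg09094964", "cg15139063")
  barcodes <- c("AAGGTT", "CCTTAA", "GGAACC", "TTCCGG", "ACACAC", "GTGTGT",
                "CAGATC", "TGCTAG")
  n_cpgs <- c(5L, 6L, 4L, 7L, 8L, 5L, 6L, 4L)
  markers <- lapply(seq_along(names8), function(i) {
    amp <- .build_amplicon(n_cpgs[i], i)
    marker_definition(names8[i], amp$seq, find_cpg_sites(amp$seq),
                      amp$primer_fwd, amp$primer_rev, barcodes[i])
  })
  marker_panel(markers, version = "fixture-8")
}
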