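#' Alignment scoring scheme
#'
#' End-to-end scoring used for read-to-amplicon alignment: match 0,
#' mismatch -6, gap open -5, gap extend -3. Under this regime a read is
#' accepted when its score is at least `-0.2 * read length`, i.e. roughly
#' one mismatch allowed per 30 bp. The bisulfite asymmetry is applied on
#' top: a read T opposite a reference C scores as a match (C-to-T
#' conversion on the sequenced strand), while a read C opposite a
#' reference T is a plain mismatch.
#'
#' @param match,mismatch,gap_open,gap_extend Score contributions
#'   (match >= 0, the others <= 0).
#' @return An `alignment_scoring` list.
#' @export
alignment_scoring <- function(match = 0, mismatch = -6,
                              gap_open = -5, gap_extend = -3) {
  structure(list(match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "alignment_scoring")
}

# 5x5 substitution matrix (A/C/G/T/N) with the bisulfite asymmetry.
.subst_matrix <- function(scoring) {
  b <- c("A", "C", "G", "T", "N")
  mat <- matrix(scoring$mismatch, 5, 5, dimnames = list(b, b))
  diag(mat) <- scoring$match
  mat["N", "N"] <- scoring$mismatch   # N never matches
  mat["T", "C"] <- scoring$match      # read T vs reference C: converted C
  mat
}

.sanitize_seq <- function(seqs) {
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) seqs[bad] <- gsub("[^ACGTN]", "N", seqs[bad])
  seqs
}

#' Demultiplex reads by barcode
#'
#' Assigns each read to the unique marker whose barcode is within
#' `max_barcode_mismatch` Hamming distance of the read prefix. A read whose
#' prefix is equally close to two barcodes within tolerance is left
#' unassigned -- a tie is never guessed. Assigned reads have the barcode
#' trimmed off.
#'
#' @param reads Data frame with columns `read_id`, `sequence`.
#' @param panel A `marker_panel` (barcodes unique).
#' @param max_barcode_mismatch Maximum Hamming distance, >= 0.
#' @return List with `assigned` (named list of per-marker data frames with
#'   barcode-trimmed sequences), `unassigned` (data frame) and `counts`
#'   (data frame of assignment counts).
#' @export
demultiplex <- function(reads, panel, max_barcode_mismatch = 1L) {
  stopifnot(inherits(panel, "marker_panel"))
  if (max_barcode_mismatch < 0) input_error("max_barcode_mismatch must be >= 0")
  seqs <- .sanitize_seq(reads$sequence)
  n <- length(seqs)
  mk_names <- names(panel$markers)
  dist <- matrix(NA_integer_, nrow = n, ncol = length(mk_names),
                 dimnames = list(NULL, mk_names))
  for (j in seq_along(mk_names)) {
    bc <- panel$markers[[j]]$barcode
    L <- nchar(bc)
    d <- rep(0L, n)
    for (i in seq_len(L))
      d <- d + (substr(seqs, i, i) != substr(bc, i, i))
    d[nchar(seqs) < L] <- L  # prefix shorter than barcode: cannot match
    dist[, j] <- d
  }
  best <- if (n) apply(dist, 1L, min) else integer(0)
  n_best <- if (n) rowSums(dist == best) else integer(0)
  ok <- n > 0 & best <= max_barcode_mismatch & n_best == 1L
  which_mk <- if (n) mk_names[apply(dist, 1L, which.min)] else character(0)
  assigned <- stats::setNames(lapply(mk_names, function(nm) {
    idx <- which(ok & which_mk == nm)
    bc_len <- nchar(panel$markers[[nm]]$barcode)
    data.frame(read_id = reads$read_id[idx],
               sequence = substr(seqs[idx], bc_len + 1L, nchar(seqs[idx])),
               stringsAsFactors = FALSE)
  }), mk_names)
  counts <- data.frame(marker = c(mk_names, "unassigned"),
                       n_reads = c(vapply(assigned, nrow, integer(1)),
                                   sum(!ok)),
                       row.names = NULL)
  list(assigned = assigned,
       unassigned = data.frame(read_id = reads$read_id[!ok],
                               sequence = seqs[!ok],
                               stringsAsFactors = FALSE),
       counts = counts)
}

# Vectorized ungapped end-to-end score for reads of the same length as the
# reference, under the bisulfite-asymmetric scheme.
.gapless_scores <- function(seqs, ref, scoring) {
  L <- nchar(ref)
  mism <- rep(0L, length(seqs))
  for (i in seq_len(L)) {
    r <- substr(seqs, i, i)
    s <- substr(ref, i, i)
    mism <- mism + !(r == s | (s == "C" & r == "T"))
  }
  mism * scoring$mismatch + (L - mism) * scoring$match
}

# Parse a global pairwise alignment into per-reference-position read
# characters plus read coordinates (to detect insertions between CpG bases).
.ref_map <- function(pattern_gapped, subject_gapped) {
  p <- strsplit(pattern_gapped, "")[[1]]
  s <- strsplit(subject_gapped, "")[[1]]
  ref_len <- sum(s != "-")
  read_char <- rep(NA_character_, ref_len)
  read_pos <- rep(NA_integer_, ref_len)
  ri <- 0L; pi <- 0L
  for (i in seq_along(s)) {
    if (p[i] != "-") pi <- pi + 1L
    if (s[i] != "-") {
      ri <- ri + 1L
      if (p[i] != "-") { read_char[ri] <- p[i]; read_pos[ri] <- pi }
    }
  }
  list(read_char = read_char, read_pos = read_pos)
}

#' Align one read to its marker reference
#'
#' Global (end-to-end) bisulfite-aware alignment of a barcode-trimmed read
#' against the unconverted amplicon reference. A read T opposite a
#' reference C is scored as a match, so both fully converted and methylated
#' molecules align at full score. The read is accepted when
#' `score >= threshold_factor * nchar(read)` (inclusive); with the default
#' factor -0.2 a 100-mer tolerates 3 mismatches (-18) but not 4 (-24).
#'
#' For reads of exactly the reference length an ungapped end-to-end
#' alignment is evaluated first and used whenever it already meets the
#' threshold; the gapped alignment (via [Biostrings::pairwiseAlignment()])
#' is computed otherwise. Sequence qualities are never consulted.
#'
#' @param read A single read sequence (barcode removed).
#' @param marker A `marker_definition`.
#' @param scoring An [alignment_scoring()] scheme.
#' @param min_read_len Reads shorter than this are rejected with reason
#'   `"too_short"` (default 30).
#' @param threshold_factor Acceptance threshold per read base (default -0.2).
#' @return An `alignment_result`: marker name, score, `accepted`, rejection
#'   `reason` (or `NA`), and the read-to-reference map used for CpG calling.
#' @export
align_read <- function(read, marker, scoring = alignment_scoring(),
                       min_read_len = 30L, threshold_factor = -0.2) {
  read <- .sanitize_seq(toupper(read))
  ref <- marker$reference_seq
  out <- structure(list(marker = marker$name, read = read,
                        score = NA_real_, accepted = FALSE,
                        reason = NA_character_, map = NULL),
                   class = "alignment_result")
  if (nchar(read) < min_read_len) {
    out$reason <- "too_short"
    return(out)
  }
  thr <- threshold_factor * nchar(read)
  if (nchar(read) == nchar(ref)) {
    gs <- .gapless_scores(read, ref, scoring)
    if (gs >= thr) {
      out$score <- gs
      out$accepted <- TRUE
      out$map <- list(read_char = strsplit(read, "")[[1]],
                      read_pos = seq_len(nchar(read)))
      return(out)
    }
  }
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(read), Biostrings::DNAString(ref),
    substitutionMatrix = .subst_matrix(scoring),
    gapOpening = -scoring$gap_open, gapExtension = -scoring$gap_extend,
    type = "global")
  out$score <- Biostrings::score(aln)
  out$accepted <- out$score >= thr
  if (!out$accepted) {
    out$reason <- "low_score"
  } else {
    out$map <- .ref_map(as.character(Biostrings::alignedPattern(aln)),
                        as.character(Biostrings::alignedSubject(aln)))
  }
  out
}

#' Call CpG methylation states from an accepted alignment
#'
#' At each marker CpG the aligned read dinucleotide is read out:
#' `"CG"` is METHYLATED, `"TG"` is UNMETHYLATED, and anything else --
#' another base, an N, a deletion, or an insertion splitting the
#' dinucleotide -- is AMBIGUOUS. A CpG not covered by the alignment is
#' AMBIGUOUS, never dropped.
#'
#' @param aln An accepted `alignment_result`.
#' @param marker The `marker_definition` the read was aligned to.
#' @return Character vector over
#'   `{"METHYLATED","UNMETHYLATED","AMBIGUOUS"}`, one element per marker
#'   CpG, in `cpg_positions` order.
#' @export
call_cpgs <- function(aln, marker) {
  if (!inherits(aln, "alignment_result") || !isTRUE(aln$accepted))
    input_error("call_cpgs() requires an accepted alignment")
  map <- aln$map
  vapply(marker$cpg_positions, function(p) {
    i <- p + 1L; j <- p + 2L
    if (j > length(map$read_char)) return("AMBIGUOUS")
    c1 <- map$read_char[i]; c2 <- map$read_char[j]
    if (is.na(c1) || is.na(c2)) return("AMBIGUOUS")
    if (map$read_pos[j] != map$read_pos[i] + 1L) return("AMBIGUOUS")
    di <- paste0(c1, c2)
    if (di == "CG") "METHYLATED" else if (di == "TG") "UNMETHYLATED"
    else "AMBIGUOUS"
  }, character(1))
}

#' Classify a molecule as fully unmethylated
#'
#' A molecule counts as colon-derived signal only when every CpG on it is
#' UNMETHYLATED. Any METHYLATED or AMBIGUOUS call makes the molecule
#' negative (but it stays in the denominator), so uncertainty can never
#' inflate the c-cfDNA estimate.
#'
#' @param calls CpG call vector from [call_cpgs()].
#' @return `TRUE` iff all calls are UNMETHYLATED.
#' @export
classify_molecule <- function(calls) {
  if (!length(calls)) input_error("empty CpG call vector")
  all(calls == "UNMETHYLATED")
}

#' Per-marker unmethylated-molecule fraction
#'
#' @param fully_unmethylated Logical vector, one element per accepted
#'   molecule of one marker.
#' @param marker Marker name (annotation only).
#' @return A `marker_counts` list: `total_molecules`,
#'   `unmethylated_molecules`, `fraction` (`NA` with a QC flag when no
#'   molecule was accepted -- never reported as 0).
#' @export
marker_fraction <- function(fully_unmethylated, marker = NA_character_) {
  total <- length(fully_unmethylated)
  unmeth <- sum(fully_unmethylated)
  structure(list(marker = marker,
                 total_molecules = total,
                 unmethylated_molecules = unmeth,
                 fraction = if (total > 0) unmeth / total else NA_real_,
                 qc_flag = if (total == 0) "no_accepted_molecules" else NA_character_),
            class = "marker_counts")
}

#' Convert an unmethylated fraction to tissue-derived copies per ml
#'
#' The marker fraction is multiplied by the sample's total cfDNA
#' concentration and by 303 to express the result as haploid genome
#' equivalents per ml: one haploid genome weighs 3.3 pg, so 1 ng/ml of
#' cfDNA corresponds to 1000/3.3 = 303 GE/ml.
#'
#' @param fraction Unmethylated-molecule fraction in \[0,1\] (`NA`
#'   propagates).
#' @param cfdna_ng_per_ml Total cfDNA concentration, ng/ml, >= 0.
#' @param ge_per_ng Conversion factor, GE per ng/ml (default 303).
#' @return Genome equivalents per ml.
#' @export
copies_per_ml <- function(fraction, cfdna_ng_per_ml, ge_per_ng = 303) {
  if (any(stats::na.omit(fraction) < 0) || any(stats::na.omit(fraction) > 1))
    input_error("fraction must lie in [0, 1]")
  if (any(stats::na.omit(cfdna_ng_per_ml) < 0))
    input_error("cfdna_ng_per_ml must be >= 0")
  fraction * cfdna_ng_per_ml * ge_per_ng
}

#' Combine per-marker copies/ml into the sample c-cfDNA score
#'
#' The per-sample value is the arithmetic mean of copies/ml over markers
#' with a defined fraction; markers with no accepted molecules are dropped
#' from the mean and their number is reported.
#'
#' @param marker_copies Numeric vector of per-marker copies/ml (`NA` for
#'   undefined markers).
#' @return List with `combined_score` (`NA` if no marker is defined),
#'   `n_contributing`, and a QC flag when the score is undefined.
#' @export
combine_markers <- function(marker_copies) {
  ok <- !is.na(marker_copies)
  list(combined_score = if (any(ok)) mean(marker_copies[ok]) else NA_real_,
       n_contributing = sum(ok),
       qc_flag = if (!any(ok)) "no_defined_markers" else NA_character_)
}

# Batch align + CpG-call all reads of one marker. Duplicate sequences are
# collapsed before alignment (amplicon data is highly redundant), and the
# gapped aligner is only invoked for reads the ungapped path cannot accept.
# Returns status ("accepted"/"too_short"/"low_score"), scores, per-read
# fully-unmethylated flags and ambiguous-call count.
.batch_align_call <- function(seqs, marker, scoring, min_read_len,
                              threshold_factor) {
  n <- length(seqs)
  k <- length(marker$cpg_positions)
  status <- rep(NA_character_, n)
  fully_unmeth <- rep(NA, n)
  n_ambiguous <- rep(NA_integer_, n)
  if (!n) return(list(status = status, fully_unmeth = fully_unmeth,
                      n_ambiguous = n_ambiguous))
  seqs <- .sanitize_seq(seqs)
  lens <- nchar(seqs)
  status[lens < min_read_len] <- "too_short"
  todo <- which(lens >= min_read_len)
  if (!length(todo)) return(list(status = status, fully_unmeth = fully_unmeth,
                                 n_ambiguous = n_ambiguous))
  uniq <- unique(seqs[todo])
  idx <- match(seqs[todo], uniq)
  ref <- marker$reference_seq
  u_status <- rep("pending", length(uniq))
  u_unmeth <- rep(NA, length(uniq))
  u_ambig <- rep(NA_integer_, length(uniq))

  call_from_chars <- function(read_char, read_pos) {
    calls <- vapply(marker$cpg_positions, function(p) {
      i <- p + 1L; j <- p + 2L
      if (j > length(read_char) || is.na(read_char[i]) || is.na(read_char[j]) ||
          read_pos[j] != read_pos[i] + 1L) return("AMBIGUOUS")
      di <- paste0(read_char[i], read_char[j])
      if (di == "CG") "METHYLATED" else if (di == "TG") "UNMETHYLATED"
      else "AMBIGUOUS"
    }, character(1))
    calls
  }

  # fast path: reads of exactly the reference length, ungapped
  same_len <- nchar(uniq) == nchar(ref)
  if (any(same_len)) {
    gs <- .gapless_scores(uniq[same_len], ref, scoring)
    thr <- threshold_factor * nchar(ref)
    pass <- gs >= thr
    ids <- which(same_len)[pass]
    if (length(ids)) {
      # vectorized dinucleotide readout at each CpG
      calls_mat <- matrix("AMBIGUOUS", length(ids), max(k, 1L))
      for (c_i in seq_len(k)) {
        p <- marker$cpg_positions[c_i]
        di <- substr(uniq[ids], p + 1L, p + 2L)
        calls_mat[, c_i] <- ifelse(di == "CG", "METHYLATED",
                                   ifelse(di == "TG", "UNMETHYLATED",
                                          "AMBIGUOUS"))
      }
      u_status[ids] <- "accepted"
      if (k > 0) {
        u_unmeth[ids] <- rowSums(calls_mat == "UNMETHYLATED") == k
        u_ambig[ids] <- rowSums(calls_mat == "AMBIGUOUS")
      } else {
        u_unmeth[ids] <- FALSE
        u_ambig[ids] <- 0L
      }
    }
  }

  # gapped fallback for everything still pending
  pend <- which(u_status == "pending")
  if (length(pend)) {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAStringSet(uniq[pend]), Biostrings::DNAString(ref),
      substitutionMatrix = .subst_matrix(scoring),
      gapOpening = -scoring$gap_open, gapExtension = -scoring$gap_extend,
      type = "global")
    sc <- Biostrings::score(aln)
    thr <- threshold_factor * nchar(uniq[pend])
    acc <- sc >= thr
    u_status[pend[!acc]] <- "low_score"
    if (any(acc)) {
      pg <- as.character(Biostrings::alignedPattern(aln))[acc]
      sg <- as.character(Biostrings::alignedSubject(aln))[acc]
      for (ii in seq_along(pg)) {
        m <- .ref_map(pg[ii], sg[ii])
        calls <- call_from_chars(m$read_char, m$read_pos)
        gi <- pend[acc][ii]
        u_status[gi] <- "accepted"
        u_unmeth[gi] <- all(calls == "UNMETHYLATED") && length(calls) > 0
        u_ambig[gi] <- sum(calls == "AMBIGUOUS")
      }
    }
  }

  status[todo] <- u_status[idx]
  fully_unmeth[todo] <- u_unmeth[idx]
  n_ambiguous[todo] <- u_ambig[idx]
  list(status = status, fully_unmeth = fully_unmeth,
       n_ambiguous = n_ambiguous)
}

#' Quantify a sample from an in-memory read table
#'
#' Runs the full readout: demultiplex by barcode, bisulfite-aware
#' end-to-end alignment with the score threshold, CG/TG CpG calling,
#' fully-unmethylated molecule classification, per-marker fractions, and
#' conversion to genome equivalents per ml combined across markers.
#'
#' @param reads Data frame with columns `read_id`, `sequence`.
#' @param panel A `marker_panel`.
#' @param sample_id Sample identifier carried into the output.
#' @param cfdna_ng_per_ml Measured total cfDNA concentration (ng/ml). When
#'   `NA` the copies/ml stage is skipped with an explicit QC flag and only
#'   fractions are reported.
#' @param max_barcode_mismatch,min_read_len,threshold_factor,scoring
#'   Pipeline parameters; see [demultiplex()] and [align_read()].
#' @return A `sample_quant` object: `per_marker` data frame (`marker`,
#'   `total_reads`, `accepted`, `rejected_too_short`, `rejected_low_score`,
#'   `unmethylated`, `fraction`, `copies_per_ml`, `ambiguous_call_rate`),
#'   `combined_score`, `n_markers_contributing`, `unassigned_reads`, and
#'   `qc_flags`.
#' @export
quantify_reads <- function(reads, panel, sample_id = "sample",
                           cfdna_ng_per_ml = NA_real_,
                           max_barcode_mismatch = 1L, min_read_len = 30L,
                           threshold_factor = -0.2,
                           scoring = alignment_scoring()) {
  dm <- demultiplex(reads, panel, max_barcode_mismatch)
  qc_flags <- character(0)
  rows <- lapply(names(panel$markers), function(nm) {
    marker <- panel$markers[[nm]]
    seqs <- dm$assigned[[nm]]$sequence
    res <- .batch_align_call(seqs, marker, scoring, min_read_len,
                             threshold_factor)
    acc <- which(res$status == "accepted")
    mc <- marker_fraction(res$fully_unmeth[acc], marker = nm)
    amb_rate <- if (length(acc) && length(marker$cpg_positions))
      sum(res$n_ambiguous[acc]) / (length(acc) * length(marker$cpg_positions))
    else NA_real_
    data.frame(marker = nm,
               total_reads = length(seqs),
               accepted = length(acc),
               rejected_too_short = sum(res$status == "too_short"),
               rejected_low_score = sum(res$status == "low_score"),
               unmethylated = mc$unmethylated_molecules,
               fraction = mc$fraction,
               ambiguous_call_rate = amb_rate,
               stringsAsFactors = FALSE)
  })
  per_marker <- do.call(rbind, rows)
  if (any(per_marker$accepted == 0))
    qc_flags <- c(qc_flags, sprintf(
      "no_accepted_molecules:%s",
      paste(per_marker$marker[per_marker$accepted == 0], collapse = ",")))
  if (is.na(cfdna_ng_per_ml)) {
    per_marker$copies_per_ml <- NA_real_
    qc_flags <- c(qc_flags, "missing_cfdna_concentration")
    comb <- list(combined_score = NA_real_, n_contributing = 0L)
  } else {
    per_marker$copies_per_ml <- copies_per_ml(per_marker$fraction,
                                              cfdna_ng_per_ml)
    comb <- combine_markers(per_marker$copies_per_ml)
    if (!is.na(comb$qc_flag %||% NA)) qc_flags <- c(qc_flags, comb$qc_flag)
  }
  structure(list(sample_id = sample_id,
                 cfdna_ng_per_ml = cfdna_ng_per_ml,
                 per_marker = per_marker,
                 combined_score = comb$combined_score,
                 n_markers_contributing = comb$n_contributing,
                 unassigned_reads = nrow(dm$unassigned),
                 demux_counts = dm$counts,
                 qc_flags = qc_flags),
            class = "sample_quant")
}

#' Quantify a sample from a FASTQ file
#'
#' @inheritParams quantify_reads
#' @param fastq_path Path to the sample's FASTQ (plain or gzip).
#' @param ... Passed to [quantify_reads()].
#' @return A `sample_quant` object; see [quantify_reads()].
#' @export
quantify_sample <- function(fastq_path, panel, sample_id = "sample",
                            cfdna_ng_per_ml = NA_real_, ...) {
  reads <- read_fastq(fastq_path)
  quantify_reads(reads, panel, sample_id = sample_id,
                 cfdna_ng_per_ml = cfdna_ng_per_ml, ...)
}

#' @export
print.sample_quant <- function(x, ...) {
  cat(sprintf("sample_quant '%s': combined c-cfDNA score %s copies/ml (%d markers)\n",
              x$sample_id,
              if (is.na(x$combined_score)) "NA"
              else format(x$combined_score, digits = 4),
              x$n_markers_contributing))
  print(x$per_marker, row.names = FALSE)
  if (length(x$qc_flags)) cat("QC:", paste(x$qc_flags, collapse = "; "), "\n")
  invisible(x)
}
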