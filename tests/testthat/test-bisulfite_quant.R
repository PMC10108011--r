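test_that("demultiplexing assigns by barcode and never guesses ties", {
  panel <- tiny_panel()
  bc1 <- panel$markers[[1]]$barcode   # AACCGG
  bc2 <- panel$markers[[2]]$barcode   # TTGGCC
  body <- bisulfite_convert_reference(panel$markers[[1]], FALSE)
  reads <- data.frame(
    read_id = c("exact", "one_mm", "all_n", "far"),
    sequence = c(paste0(bc1, body),
                 paste0(mutate_at(bc1, 1, "T"), body),
                 paste0("NNNNNN", body),
                 paste0("GGAATT", body)))
  dm <- demultiplex(reads, panel, max_barcode_mismatch = 1)
  expect_identical(dm$assigned$mkA$read_id, c("exact", "one_mm"))
  # barcode is trimmed from assigned reads
  expect_identical(dm$assigned$mkA$sequence, rep(body, 2))
  expect_setequal(dm$unassigned$read_id, c("all_n", "far"))
  # conservation of reads across bins
  expect_identical(sum(dm$counts$n_reads), nrow(reads))

  # a prefix equidistant from two barcodes must stay unassigned
  panel2 <- marker_panel(list(
    marker_definition("t1", panel$markers[[1]]$reference_seq,
                      panel$markers[[1]]$cpg_positions, c(0L, 16L),
                      c(32L, 48L), "AAAAAA"),
    marker_definition("t2", panel$markers[[2]]$reference_seq,
                      panel$markers[[2]]$cpg_positions, c(0L, 16L),
                      c(36L, 52L), "AAAATT")))
  tie <- data.frame(read_id = "tie", sequence = paste0("AAAAAT", body))
  dm2 <- demultiplex(tie, panel2, max_barcode_mismatch = 1)
  expect_identical(nrow(dm2$unassigned), 1L)
})

test_that("alignment accepts at the -0.2 x length score threshold", {
  m <- marker_100()
  template <- bisulfite_convert_reference(m, FALSE)
  # positions where the reference is A: substitution to G is a real mismatch
  a_pos <- which(strsplit(m$reference_seq, "")[[1]] == "A")

  perfect <- align_read(template, m)
  expect_identical(perfect$score, 0)
  expect_true(perfect$accepted)

  meth <- align_read(bisulfite_convert_reference(m, TRUE), m)
  expect_identical(meth$score, 0)   # CpG C against reference C is a match
  expect_true(meth$accepted)

  three <- align_read(mutate_at(template, a_pos[1:3], "G"), m)
  expect_identical(three$score, -18)
  expect_true(three$accepted)       # -18 >= -0.2 * 100

  four <- align_read(mutate_at(template, a_pos[1:4], "G"), m)
  expect_false(four$accepted)       # -24 < -20
  expect_identical(four$reason, "low_score")

  # boundary is inclusive: score == threshold is accepted
  one <- mutate_at(template, a_pos[1], "G")
  expect_true(align_read(one, m, threshold_factor = -0.06)$accepted)  # -6 == -6
  expect_false(align_read(one, m, threshold_factor = -0.059)$accepted)

  # conversion asymmetry is one-way: read C opposite reference T mismatches
  t_pos <- which(strsplit(m$reference_seq, "")[[1]] == "T")
  c_read <- align_read(mutate_at(template, t_pos[1], "C"), m)
  expect_identical(c_read$score, -6)

  expect_identical(align_read("ACGT", m)$reason, "too_short")
})

test_that("CpG calls read CG as methylated, TG as unmethylated, else ambiguous", {
  m <- tiny_panel()$markers[[1]]
  k <- length(m$cpg_positions)
  unmeth <- bisulfite_convert_reference(m, FALSE)
  meth <- bisulfite_convert_reference(m, TRUE)

  calls_u <- call_cpgs(align_read(unmeth, m), m)
  expect_identical(calls_u, rep("UNMETHYLATED", k))
  expect_true(classify_molecule(calls_u))

  calls_m <- call_cpgs(align_read(meth, m), m)
  expect_identical(calls_m, rep("METHYLATED", k))
  expect_false(classify_molecule(calls_m))

  # first CpG methylated, rest unmethylated
  mixed <- mutate_at(unmeth, m$cpg_positions[1] + 1L, "C")
  expect_identical(call_cpgs(align_read(mixed, m), m),
                   c("METHYLATED", rep("UNMETHYLATED", k - 1)))

  # an AG dinucleotide is neither CG nor TG
  amb <- mutate_at(unmeth, m$cpg_positions[1] + 1L, "A")
  calls_a <- call_cpgs(align_read(amb, m), m)
  expect_identical(calls_a[1], "AMBIGUOUS")
  expect_false(classify_molecule(calls_a))

  expect_error(classify_molecule(character(0)), class = "ccfdna_input_error")
})

test_that("gapped alignments cover CpGs or call them ambiguous", {
  m <- marker_100()
  template <- bisulfite_convert_reference(m, FALSE)
  # delete the G of the first CpG: read is 99 bp, needs a gapped alignment
  ch <- strsplit(template, "")[[1]]
  del <- paste(ch[-(m$cpg_positions[1] + 2L)], collapse = "")
  aln <- align_read(del, m)
  expect_true(aln$accepted)  # one short gap is within threshold
  calls <- call_cpgs(aln, m)
  # the gap may sit at any of the equivalent repeat units, but exactly one
  # CpG must lose its dinucleotide and the molecule must not count as
  # fully unmethylated
  expect_identical(sum(calls == "AMBIGUOUS"), 1L)
  expect_identical(sum(calls == "UNMETHYLATED"), length(calls) - 1L)
  expect_false(classify_molecule(calls))
})

test_that("fractions, unit conversion and marker combination follow the rules", {
  mc <- marker_fraction(c(rep(TRUE, 2), rep(FALSE, 8)))
  expect_identical(mc$fraction, 0.2)
  expect_identical(marker_fraction(rep(FALSE, 10))$fraction, 0)
  empty <- marker_fraction(logical(0))
  expect_true(is.na(empty$fraction))
  expect_identical(empty$qc_flag, "no_accepted_molecules")

  expect_identical(copies_per_ml(1, 1), 303)
  expect_identical(copies_per_ml(0, 50), 0)
  expect_equal(copies_per_ml(0.05, 20), 303)
  expect_true(is.na(copies_per_ml(NA_real_, 10)))
  expect_error(copies_per_ml(1.5, 1), class = "ccfdna_input_error")
  # strictly increasing in both arguments
  expect_true(copies_per_ml(0.3, 10) > copies_per_ml(0.2, 10))
  expect_true(copies_per_ml(0.3, 11) > copies_per_ml(0.3, 10))

  expect_identical(combine_markers(c(0, 10))$combined_score, 5)
  cm <- combine_markers(c(10, NA))
  expect_identical(cm$combined_score, 10)
  expect_identical(cm$n_contributing, 1L)
  expect_identical(combine_markers(c(NA_real_, NA_real_))$qc_flag,
                   "no_defined_markers")
})

test_that("quantification conserves reads and matches ground truth exactly without noise", {
  panel <- tiny_panel()
  cfg <- plasma_mixture_config(colon_fraction = 0.3,
                               n_molecules_per_marker = 400,
                               conversion_efficiency = 1,
                               inappropriate_conversion_rate = 0,
                               seq_error_rate = 0, seed = 31)
  sim <- simulate_sample_reads(panel, cfg)
  q <- quantify_reads(sim$reads, panel, cfdna_ng_per_ml = 10)

  for (nm in names(panel$markers)) {
    truth_frac <- mean(sim$truth$origin[sim$truth$marker == nm] == "colon")
    row <- q$per_marker[q$per_marker$marker == nm, ]
    expect_identical(row$fraction, truth_frac)  # exact, not approximate
    expect_identical(row$accepted, 400L)
  }
  # conservation: accepted + rejected + unassigned == input reads
  expect_identical(sum(q$per_marker$accepted) +
                     sum(q$per_marker$rejected_too_short) +
                     sum(q$per_marker$rejected_low_score) +
                     q$unassigned_reads,
                   nrow(sim$reads))
  expect_equal(q$combined_score,
               mean(q$per_marker$fraction) * 10 * 303)
})

test_that("full-sample quantification from FASTQ hits the closed-form score", {
  panel <- tiny_panel()
  cfg <- plasma_mixture_config(colon_fraction = 1,
                               n_molecules_per_marker = 100,
                               conversion_efficiency = 1,
                               inappropriate_conversion_rate = 0,
                               seq_error_rate = 0, seed = 5)
  sim <- simulate_sample_reads(panel, cfg)
  fq <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(sim$reads, fq)
  q <- quantify_sample(fq, panel, sample_id = "s1", cfdna_ng_per_ml = 10)
  expect_true(all(q$per_marker$fraction == 1))
  expect_equal(q$combined_score, 3030)  # 1.0 x 10 ng/ml x 303

  # missing concentration: fractions reported, copies/ml skipped with a flag
  q2 <- quantify_sample(fq, panel, cfdna_ng_per_ml = NA)
  expect_true(all(q2$per_marker$fraction == 1))
  expect_true(all(is.na(q2$per_marker$copies_per_ml)))
  expect_true("missing_cfdna_concentration" %in% q2$qc_flags)
})
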