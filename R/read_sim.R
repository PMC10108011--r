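# Run code with a private, restored RNG state so simulators are seeded
# without disturbing the caller's random stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

#' Configuration for the plasma read mixture simulator
#'
#' Describes a plasma sample as a two-component molecule mixture per marker:
#' a colon-derived component, unmethylated at all marker CpGs, spiked at
#' `colon_fraction` into a background that is fully methylated at those
#' CpGs. Molecules pass through bisulfite conversion with imperfect
#' chemistry and then through sequencing with substitution errors.
#'
#' @param colon_fraction Proportion in \[0,1\] of molecules of colon origin.
#' @param n_molecules_per_marker Molecules simulated for each marker.
#' @param conversion_efficiency Probability that an unmethylated cytosine is
#'   converted to T. 0.995 reflects routine bisulfite kit performance.
#' @param inappropriate_conversion_rate Probability that a methylated CpG
#'   cytosine is wrongly converted to T.
#' @param seq_error_rate Per-base substitution error probability.
#' @param seed Integer seed; a fixed seed makes the output bit-identical.
#' @return A `plasma_mixture_config` list.
#' @export
plasma_mixture_config <- function(colon_fraction = 0.05,
                                  n_molecules_per_marker = 2000L,
                                  conversion_efficiency = 0.995,
                                  inappropriate_conversion_rate = 0.005,
                                  seq_error_rate = 0.003,
                                  seed = 1L) {
  probs <- c(colon_fraction, conversion_efficiency,
             inappropriate_conversion_rate, seq_error_rate)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1))
    input_error("all mixture probabilities must lie in [0, 1]")
  if (n_molecules_per_marker < 0)
    input_error("n_molecules_per_marker must be >= 0")
  structure(list(colon_fraction = colon_fraction,
                 n_molecules_per_marker = as.integer(n_molecules_per_marker),
                 conversion_efficiency = conversion_efficiency,
                 inappropriate_conversion_rate = inappropriate_conversion_rate,
                 seq_error_rate = seq_error_rate,
                 seed = as.integer(seed)),
            class = "plasma_mixture_config")
}

# Simulate one marker's molecules as a character matrix operation.
# Returns list(sequences = character, origin = character)
.simulate_marker_molecules <- function(marker, cfg) {
  n <- cfg$n_molecules_per_marker
  if (n == 0L)
    return(list(sequences = character(0), origin = character(0)))
  ref <- strsplit(marker$reference_seq, "")[[1]]
  L <- length(ref)
  origin <- ifelse(stats::runif(n) < cfg$colon_fraction, "colon", "background")

  mat <- matrix(rep(ref, each = n), nrow = n)
  is_c <- ref == "C"
  is_cpg_c <- rep(FALSE, L)
  if (length(marker$cpg_positions)) is_cpg_c[marker$cpg_positions + 1L] <- TRUE

  # bisulfite chemistry: unmethylated C -> T with conversion_efficiency;
  # methylated CpG C -> T with inappropriate_conversion_rate
  ce <- cfg$conversion_efficiency
  icr <- cfg$inappropriate_conversion_rate
  degenerate <- all(c(ce, icr) %in% c(0, 1))
  for (j in which(is_c)) {
    if (is_cpg_c[j]) {
      conv <- if (degenerate) ifelse(origin == "colon", ce == 1, icr == 1)
      else {
        u <- stats::runif(n)
        ifelse(origin == "colon", u < ce, u < icr)
      }
    } else {
      conv <- if (ce %in% c(0, 1)) rep(ce == 1, n) else stats::runif(n) < ce
    }
    mat[conv, j] <- "T"
  }

  # read = barcode + converted molecule; substitution errors over all bases
  bc <- strsplit(marker$barcode, "")[[1]]
  full <- cbind(matrix(rep(bc, each = n), nrow = n), mat)
  if (cfg$seq_error_rate > 0) {
    hit <- which(stats::runif(length(full)) < cfg$seq_error_rate)
    if (length(hit)) {
      bases <- c("A", "C", "G", "T")
      # substitute with a uniformly chosen different base
      cur <- full[hit]
      sub <- bases[(match(cur, bases) - 1L +
                      sample.int(3L, length(hit), replace = TRUE)) %% 4L + 1L]
      full[hit] <- sub
    }
  }
  seqs <- do.call(paste0, lapply(seq_len(ncol(full)), function(j) full[, j]))
  list(sequences = seqs, origin = origin)
}

#' Simulate a multiplexed bisulfite-amplicon sequencing run
#'
#' Draws `n_molecules_per_marker` molecules per marker from the two-component
#' plasma mixture in `cfg`, applies in-silico bisulfite conversion and
#' sequencing error, prepends the marker barcode and emits FASTQ-style
#' records with uniform dummy qualities (downstream analysis ignores
#' qualities).
#'
#' @param panel A `marker_panel`.
#' @param cfg A `plasma_mixture_config`.
#' @return A list with `reads` (data.frame: `read_id`, `sequence`) and
#'   `truth` (data.frame: `read_id`, `marker`, `origin`) plus per-marker
#'   origin counts in `truth_counts`.
#' @export
simulate_sample_reads <- function(panel, cfg) {
  stopifnot(inherits(panel, "marker_panel"),
            inherits(cfg, "plasma_mixture_config"))
  with_seed(cfg$seed, {
    per <- lapply(panel$markers, .simulate_marker_molecules, cfg = cfg)
    reads <- do.call(rbind, lapply(names(per), function(nm) {
      n <- length(per[[nm]]$sequences)
      if (!n) return(NULL)
      data.frame(read_id = sprintf("%s_mol%06d", nm, seq_len(n)),
                 sequence = per[[nm]]$sequences,
                 stringsAsFactors = FALSE)
    }))
    truth <- do.call(rbind, lapply(names(per), function(nm) {
      n <- length(per[[nm]]$origin)
      if (!n) return(NULL)
      data.frame(read_id = sprintf("%s_mol%06d", nm, seq_len(n)),
                 marker = nm, origin = per[[nm]]$origin,
                 stringsAsFactors = FALSE)
    }))
    if (is.null(reads))
      reads <- data.frame(read_id = character(0), sequence = character(0))
    if (is.null(truth))
      truth <- data.frame(read_id = character(0), marker = character(0),
                          origin = character(0))
    counts <- if (nrow(truth))
      as.data.frame(table(marker = truth$marker, origin = truth$origin),
                    stringsAsFactors = FALSE)
    else data.frame(marker = character(0), origin = character(0),
                    Freq = integer(0))
    list(reads = reads, truth = truth, truth_counts = counts)
  })
}

#' Write reads as FASTQ
#'
#' Standard 4-line records; every base gets quality "I" since qualities are
#' ignored by the quantification. Paths ending in `.gz` are compressed.
#'
#' @param reads Data frame with columns `read_id` and `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$sequence)
  names(x) <- reads$read_id
  quals <- Biostrings::BStringSet(vapply(nchar(reads$sequence),
                                         function(n) strrep("I", n),
                                         character(1)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = quals,
                              compress = endsWith(path, ".gz"))
  invisible(path)
}

#' Read a FASTQ file into the read table used by the pipeline
#'
#' @param path FASTQ path (plain or gzip).
#' @return Data frame with columns `read_id` and `sequence`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) input_error(sprintf("FASTQ not found: %s", path))
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  data.frame(read_id = names(x), sequence = as.character(x),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write simulation ground truth as CSV
#' @param truth Data frame from [simulate_sample_reads()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  utils::write.csv(truth, path, row.names = FALSE)
  invisible(path)
}
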