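# Shared fixtures and independent oracles used across test files.

# Small 2-marker panel for fast unit tests. Sequences are hand-built so that
# every CG is a designed CpG and primers satisfy the CH rule.
tiny_panel <- function() {
  #          primer_fwd (16)        mid                     primer_rev (16)
  s1 <- paste0("ACTTACTTACTTACTT", "ATTACGTTATCGATTA", "TCAATCAATCAATCAA")
  s2 <- paste0("TCTATCTATCTATCTA", "TAACGATTTACGTTAACGTT", "AACTAACTAACTAACT")
  m1 <- marker_definition("mkA", s1, find_cpg_sites(s1),
                          c(0L, 16L), c(nchar(s1) - 16L, nchar(s1)), "AACCGG")
  m2 <- marker_definition("mkB", s2, find_cpg_sites(s2),
                          c(0L, 16L), c(nchar(s2) - 16L, nchar(s2)), "TTGGCC")
  marker_panel(list(m1, m2), version = "tiny")
}

# Marker with a 100 bp reference (for alignment-threshold arithmetic).
marker_100 <- function() {
  s <- paste0("ACTTACTTACTTACTTACTT",              # fwd primer, 20
              strrep("ATTACG", 5),                 # 5 CpGs, 30
              strrep("ATTATA", 5),                 # filler, 30
              "TCAATCAATCAATCAATCAA")              # rev primer, 20
  stopifnot(nchar(s) == 100)
  marker_definition("mk100", s, find_cpg_sites(s), c(0L, 20L),
                    c(80L, 100L), "ACGTCA")
}

# Replace characters of a string at 1-based positions.
mutate_at <- function(seq, pos, to) {
  ch <- strsplit(seq, "")[[1]]
  ch[pos] <- to
  paste(ch, collapse = "")
}

# ---- independent oracles ----------------------------------------------------

# Fisher two-sided p by full hypergeometric enumeration.
fisher_brute <- function(tab) {
  a <- tab[1, 1]
  m <- sum(tab[1, ]); n2 <- sum(tab[2, ]); k <- sum(tab[, 1])
  supp <- max(0, k - n2):min(k, m)
  probs <- stats::dhyper(supp, m, n2, k)
  p_obs <- stats::dhyper(a, m, n2, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Exact Mann-Whitney p by enumerating all assignments of ranks to group A.
mw_brute <- function(a, b, alternative) {
  n <- length(a); m <- length(b)
  r <- rank(c(a, b))
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  combs <- utils::combn(n + m, n)
  u_all <- apply(combs, 2, function(idx) sum(sort(r)[idx]) - n * (n + 1) / 2)
  less <- mean(u_all <= u_obs)
  greater <- mean(u_all >= u_obs)
  switch(alternative,
         "one-sided-less" = less,
         "one-sided-greater" = greater,
         "two-sided" = min(1, 2 * (if (u_obs > n * m / 2) greater else less)))
}

# AUC as concordant-pair probability with ties counted 1/2.
auc_pairs <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(cmp)
}
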