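# Naive string-multiset reference implementation of the whole scan, kept
# deliberately independent of the package's encoded/compiled path: k-mers
# are plain character strings, canonicalised by string comparison, counted
# with table(). Only usable on toy problems.

oracle_revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTacgt", "TGCAtgca",
           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

# canonical k-mer strings of one sequence, invalid windows dropped
oracle_kmers <- function(seq, k) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n < k) return(character(0))
  w <- substring(seq, 1:(n - k + 1), k:n)
  w <- w[!grepl("[^ACGT]", w)]
  if (length(w) == 0) return(character(0))
  rc <- oracle_revcomp(w)
  pmin(w, rc)
}

oracle_read_set <- function(reads, k, min_read_count) {
  tab <- table(unlist(lapply(reads, oracle_kmers, k = k)))
  names(tab)[tab >= min_read_count]
}

# full scan: per-scaffold records with the same columns as ygs_scan()
oracle_scan <- function(assembly, male_reads, female_reads, params) {
  kp <- params$kmer
  keep <- nchar(assembly) >= kp$min_scaffold_len
  assembly <- assembly[keep]
  tab <- table(unlist(lapply(assembly, oracle_kmers, k = kp$k)))
  single <- names(tab)[tab == 1]
  repet <- names(tab)[tab > 1]
  fem <- oracle_read_set(female_reads, kp$k, kp$min_read_count)
  mal <- oracle_read_set(male_reads, kp$k, kp$min_read_count)
  rec <- do.call(rbind, lapply(names(assembly), function(id) {
    km <- unique(oracle_kmers(assembly[[id]], kp$k))
    nd <- length(km)
    sc <- setdiff(km, repet)
    ns <- length(sc)
    absent_both <- sum(!(km %in% fem) & !(km %in% mal))
    data.frame(
      scaffold_id = id,
      length_bp = nchar(assembly[[id]]),
      n_distinct = nd,
      n_repetitive = nd - ns,
      n_single_copy = ns,
      repeat_fraction = if (nd > 0) (nd - ns) / nd else NA_real_,
      pct_absent_both = if (nd > 0) 100 * absent_both / nd else NA_real_,
      pct_unmatched_female = if (ns > 0) 100 * sum(!(sc %in% fem)) / ns else NA_real_,
      pct_unmatched_male = if (ns > 0) 100 * sum(!(sc %in% mal)) / ns else NA_real_,
      stringsAsFactors = FALSE)
  }))
  rec$qc_pass <- !is.na(rec$pct_absent_both) &
    rec$pct_absent_both <= params$low_quality_max_pct
  thr <- params$candidate_min_unmatched_pct
  rec$is_candidate_xy <- rec$qc_pass & !is.na(rec$pct_unmatched_female) &
    rec$pct_unmatched_female > thr
  rec$is_candidate_zw <- rec$qc_pass & !is.na(rec$pct_unmatched_male) &
    rec$pct_unmatched_male > thr
  rec
}

# random toy problem generator used by the oracle-equivalence tests
random_dna <- function(n) paste(sample(c("A", "C", "G", "T", "N"), n,
                                       replace = TRUE,
                                       prob = c(0.24, 0.24, 0.24, 0.24, 0.04)),
                                collapse = "")

random_toy <- function(k) {
  n_scaf <- sample(2:6, 1)
  assembly <- vapply(seq_len(n_scaf),
                     function(i) random_dna(sample(seq(k, 400), 1)),
                     character(1))
  names(assembly) <- paste0("scf", seq_len(n_scaf))
  # reads: fragments of the scaffolds (both strands) plus random noise
  sample_reads <- function(n_reads) {
    if (n_reads == 0) return(character(0))
    src <- sample(names(assembly), n_reads, replace = TRUE)
    vapply(src, function(id) {
      L <- nchar(assembly[[id]])
      rl <- min(L, sample(seq(k, 60), 1))
      start <- sample.int(L - rl + 1, 1)
      r <- substr(assembly[[id]], start, start + rl - 1)
      if (stats::runif(1) < 0.5) oracle_revcomp(r) else r
    }, character(1), USE.NAMES = FALSE)
  }
  noise <- function(n) vapply(seq_len(n),
                              function(i) random_dna(sample(k:40, 1)),
                              character(1))
  male <- c(sample_reads(sample(5:40, 1)), noise(sample(0:5, 1)))
  female <- c(sample_reads(sample(5:40, 1)), noise(sample(0:5, 1)))
  list(assembly = assembly, male = male, female = female)
}

# small, fast simulator spec shared by module tests
small_spec <- function(system = "XY", seed = 7L, ...) {
  sim_spec(system = system,
           autosome_lengths = c(60000L, 40000L),
           x_length = 30000L,
           y_length = 20000L,
           scaffold_length = 5000L,
           seed = seed,
           ...)
}

expect_records_equal <- function(got, want) {
  got <- got[order(got$scaffold_id), ]
  want <- want[order(want$scaffold_id), ]
  for (col in c("scaffold_id", "length_bp", "n_distinct", "n_repetitive",
                "n_single_copy", "qc_pass", "is_candidate_xy",
                "is_candidate_zw"))
    expect_equal(unname(got[[col]]), unname(want[[col]]),
                 info = paste("column", col))
  for (col in c("repeat_fraction", "pct_absent_both",
                "pct_unmatched_female", "pct_unmatched_male"))
    expect_equal(unname(got[[col]]), unname(want[[col]]),
                 tolerance = 1e-12, info = paste("column", col))
}
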