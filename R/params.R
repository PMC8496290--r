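#' K-mer scan parameters
#'
#' Bundle of the three knobs shared by the indexing and scanning steps:
#' the k-mer word length, the minimum multiplicity for a k-mer to count as
#' "present" in a sex's read set, and the minimum scaffold length retained
#' from the assembly.
#'
#' @param k Word length in bases. Must lie in `[2, 31]` so that a canonical
#'   code fits in a 62-bit integer. Default 16, the word length at which a
#'   random match in a ~0.5 Gb genome is already unlikely.
#' @param min_read_count Minimum total multiplicity across one sex's reads
#'   for a k-mer to be a member of that sex's set. Default 2: at ~20x
#'   coverage a genuine genomic k-mer is seen many times while most
#'   sequencing-error k-mers are singletons.
#' @param min_scaffold_len Minimum scaffold length (bp) retained from the
#'   assembly. Default 200.
#' @return An object of class `kmer_params`.
#' @examples
#' kmer_params(k = 16)
#' @export
kmer_params <- function(k = 16L, min_read_count = 2L, min_scaffold_len = 200L) {
  k <- as.integer(k)
  min_read_count <- as.integer(min_read_count)
  min_scaffold_len <- as.integer(min_scaffold_len)
  if (is.na(k) || k < 2L || k > 31L)
    stop("configuration error: k must be an integer in [2, 31]", call. = FALSE)
  if (is.na(min_read_count) || min_read_count < 1L)
    stop("configuration error: min_read_count must be >= 1", call. = FALSE)
  if (is.na(min_scaffold_len) || min_scaffold_len < k)
    stop("configuration error: min_scaffold_len must be >= k", call. = FALSE)
  structure(list(k = k, min_read_count = min_read_count,
                 min_scaffold_len = min_scaffold_len),
            class = "kmer_params")
}

#' @export
print.kmer_params <- function(x, ...) {
  cat(sprintf("k-mer parameters: k = %d, min_read_count = %d, min_scaffold_len = %d bp\n",
              x$k, x$min_read_count, x$min_scaffold_len))
  invisible(x)
}

#' Scan thresholds
#'
#' Thresholds applied to the per-scaffold statistics. Both comparisons are
#' strict: a scaffold fails QC only when *more than* `low_quality_max_pct`
#' of its distinct k-mers are absent from both sexes' reads, and becomes a
#' candidate only when *more than* `candidate_min_unmatched_pct` of its
#' single-copy k-mers are unmatched in the relevant sex's reads.
#'
#' @param low_quality_max_pct Maximum tolerated percentage of a scaffold's
#'   distinct k-mers absent from the union of the two read sets (default 10).
#'   Such k-mers are attributable to assembly error, so scaffolds beyond this
#'   are flagged low quality and excluded from candidacy.
#' @param candidate_min_unmatched_pct Percentage of single-copy k-mers that
#'   must be unmatched for a scaffold to be a sex-limited candidate
#'   (default 70).
#' @param kmer Inherited [kmer_params()].
#' @return An object of class `scan_params`.
#' @export
scan_params <- function(low_quality_max_pct = 10,
                        candidate_min_unmatched_pct = 70,
                        kmer = kmer_params()) {
  if (!inherits(kmer, "kmer_params"))
    stop("configuration error: kmer must be a kmer_params object", call. = FALSE)
  for (v in c(low_quality_max_pct, candidate_min_unmatched_pct))
    if (!is.numeric(v) || is.na(v) || v < 0 || v > 100)
      stop("configuration error: thresholds must lie in [0, 100]", call. = FALSE)
  structure(list(low_quality_max_pct = as.numeric(low_quality_max_pct),
                 candidate_min_unmatched_pct = as.numeric(candidate_min_unmatched_pct),
                 kmer = kmer),
            class = "scan_params")
}

#' @export
print.scan_params <- function(x, ...) {
  cat(sprintf("scan thresholds: low-quality > %.4g%% absent-both; candidate > %.4g%% unmatched\n",
              x$low_quality_max_pct, x$candidate_min_unmatched_pct))
  print(x$kmer)
  invisible(x)
}

#' Verdict rule for calling the sex-chromosome system
#'
#' The distribution pattern of the two scans is summarised into candidate
#' counts and base-pair totals per side; this rule converts those summaries
#' into an XY / ZW / inconclusive verdict. A side wins only when it reaches
#' both absolute minima and dominates the other side in both total candidate
#' sequence and candidate count.
#'
#' The count minimum is deliberately small: a larger one would make the
#' verdict depend on how fragmented the sex-limited chromosome happens to be
#' in the assembly, penalising well-assembled genomes. Robustness against
#' repeat-artifact tails comes from the bp minimum and the two dominance
#' ratios, which such tails do not satisfy.
#'
#' @param min_candidates Minimum number of candidate scaffolds on the winning
#'   side (default 5).
#' @param min_bp Minimum summed candidate length in bp (default 50000).
#' @param bp_ratio Required ratio of winning to losing side total bp
#'   (default 5).
#' @param count_ratio Required ratio of candidate counts (default 3).
#' @return An object of class `verdict_rule`.
#' @export
verdict_rule <- function(min_candidates = 5, min_bp = 50000,
                         bp_ratio = 5, count_ratio = 3) {
  if (min_candidates < 0 || min_bp < 0)
    stop("configuration error: minima must be >= 0", call. = FALSE)
  if (bp_ratio < 1 || count_ratio < 1)
    stop("configuration error: ratios must be >= 1", call. = FALSE)
  structure(list(min_candidates = as.numeric(min_candidates),
                 min_bp = as.numeric(min_bp),
                 bp_ratio = as.numeric(bp_ratio),
                 count_ratio = as.numeric(count_ratio)),
            class = "verdict_rule")
}

#' @export
print.verdict_rule <- function(x, ...) {
  cat(sprintf("verdict rule: >= %g candidates, >= %g bp, bp ratio >= %g, count ratio >= %g\n",
              x$min_candidates, x$min_bp, x$bp_ratio, x$count_ratio))
  invisible(x)
}
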