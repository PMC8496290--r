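#' Scan a single scaffold against both sexes' read k-mer sets
#'
#' Decomposes the scaffold into distinct canonical k-mers, removes those in
#' the assembly's repetitive set, and computes the two unmatched percentages:
#' the fraction of the scaffold's single-copy k-mers absent from the female
#' read set (high for Y-linked scaffolds) and from the male read set (high
#' for W-linked scaffolds). Also computes the quality statistic
#' `pct_absent_both`, the fraction of all distinct k-mers found in neither
#' sex's reads — such k-mers come from assembly error, since a genuine k-mer
#' of either sex would be seen in that sex's reads.
#'
#' @param seq Scaffold sequence (single string).
#' @param scaffold_id Scaffold identifier.
#' @param index An [build_assembly_index()] result; the scaffold should be
#'   one of its retained scaffolds.
#' @param female,male [build_read_kmer_set()] results for the two sexes.
#' @param params A [scan_params()] object.
#' @return One-row data frame (a scaffold record) with count, percentage,
#'   QC and candidacy columns. Percentages over single-copy k-mers are `NA`
#'   when the scaffold has none.
#' @export
scan_scaffold <- function(seq, scaffold_id, index, female, male,
                          params = scan_params()) {
  stopifnot(inherits(index, "assembly_index"),
            inherits(female, "read_kmer_set"),
            inherits(male, "read_kmer_set"),
            inherits(params, "scan_params"))
  if (female$k != index$k || male$k != index$k)
    stop("configuration error: k mismatch between index (", index$k,
         ") and read sets (", female$k, ", ", male$k, ")", call. = FALSE)
  cnt <- cpp_scan_counts(seq, index$single_copy$ptr, index$repetitive$ptr,
                         female$set$ptr, male$set$ptr)
  rec <- data.frame(
    scaffold_id = scaffold_id,
    length_bp = nchar(seq),
    n_distinct = cnt[["n_distinct"]],
    n_repetitive = cnt[["n_repetitive"]],
    n_single_copy = cnt[["n_single_copy"]],
    stringsAsFactors = FALSE)
  rec$repeat_fraction <- ifelse(rec$n_distinct > 0,
                                rec$n_repetitive / rec$n_distinct, NA_real_)
  rec$pct_absent_both <- ifelse(rec$n_distinct > 0,
                                100 * cnt[["n_absent_both"]] / rec$n_distinct,
                                NA_real_)
  rec$pct_unmatched_female <- ifelse(rec$n_single_copy > 0,
                                     100 * cnt[["n_unmatched_female"]] / rec$n_single_copy,
                                     NA_real_)
  rec$pct_unmatched_male <- ifelse(rec$n_single_copy > 0,
                                   100 * cnt[["n_unmatched_male"]] / rec$n_single_copy,
                                   NA_real_)
  rec <- apply_qc(rec, params)
  classify_candidates(rec, params)
}

#' Apply the low-quality filter
#'
#' A scaffold fails QC when strictly more than `low_quality_max_pct` of its
#' distinct k-mers are absent from both sexes' reads (the boundary value
#' itself passes). Scaffolds with no valid k-mers cannot be assessed and are
#' marked as failing.
#'
#' @param records Scaffold record data frame (one or more rows).
#' @param params A [scan_params()] object.
#' @return `records` with the `qc_pass` column set.
#' @export
apply_qc <- function(records, params = scan_params()) {
  records$qc_pass <- !is.na(records$pct_absent_both) &
    records$pct_absent_both <= params$low_quality_max_pct
  records
}

#' Flag sex-limited candidate scaffolds
#'
#' A scaffold is an XY-side (putative Y) candidate when it passes QC and
#' strictly more than `candidate_min_unmatched_pct` of its single-copy
#' k-mers are unmatched in the female reads; the ZW side mirrors this with
#' the male reads. Scaffolds failing QC, or with undefined statistics, are
#' never candidates.
#'
#' @inheritParams apply_qc
#' @return `records` with `is_candidate_xy` and `is_candidate_zw` set.
#' @export
classify_candidates <- function(records, params = scan_params()) {
  thr <- params$candidate_min_unmatched_pct
  records$is_candidate_xy <- records$qc_pass &
    !is.na(records$pct_unmatched_female) & records$pct_unmatched_female > thr
  records$is_candidate_zw <- records$qc_pass &
    !is.na(records$pct_unmatched_male) & records$pct_unmatched_male > thr
  records
}

#' Dual genome scan of an assembly against male and female reads
#'
#' The main entry point. Builds the assembly single-copy/repetitive k-mer
#' partition once, the two read k-mer sets once, and scans every retained
#' scaffold once, producing both per-scaffold unmatched percentages in a
#' single pass (mathematically identical to two separate scans). The result
#' is deterministic for fixed inputs and parameters.
#'
#' @param assembly FASTA path or named character vector of scaffolds.
#' @param male_reads,female_reads FASTQ/FASTA path(s), raw read sequence
#'   vectors, or prebuilt [build_read_kmer_set()] objects.
#' @param params A [scan_params()] object.
#' @param exclude_ids Optional scaffold-ID exclusion list (vector or file).
#' @param keep_sequences Keep the retained scaffold sequences in the result
#'   so candidate FASTA export is possible (default TRUE).
#' @return An object of class `ygs_scan`: `records` (one row per retained
#'   scaffold), `params`, `index_summary`, low-quality totals, and the read
#'   set labels.
#' @export
ygs_scan <- function(assembly, male_reads, female_reads,
                     params = scan_params(), exclude_ids = NULL,
                     keep_sequences = TRUE) {
  stopifnot(inherits(params, "scan_params"))
  seqs <- as_assembly_seqs(assembly)
  index <- build_assembly_index(seqs, params$kmer, exclude_ids = exclude_ids)
  female <- as_read_set(female_reads, params$kmer, "female")
  male <- as_read_set(male_reads, params$kmer, "male")
  retained <- seqs[names(index$scaffold_lengths)]
  rec_list <- lapply(names(retained), function(id) {
    scan_scaffold(retained[[id]], id, index, female, male, params)
  })
  records <- do.call(rbind, rec_list)
  records <- records[scan_tsv_columns()]
  low <- !records$qc_pass
  structure(list(
    records = records,
    params = params,
    female_label = female$sex_label,
    male_label = male$sex_label,
    n_low_quality = sum(low),
    bp_low_quality = sum(as.numeric(records$length_bp[low])),
    index_summary = list(
      k = index$k,
      n_scaffolds = length(index$scaffold_lengths),
      total_bp = sum(as.numeric(index$scaffold_lengths)),
      n_single_copy = kmer_set_size(index$single_copy),
      n_repetitive = kmer_set_size(index$repetitive),
      n_excluded = index$n_excluded,
      n_too_short = index$n_too_short,
      female_kmers = female$n_members,
      male_kmers = male$n_members),
    sequences = if (keep_sequences) retained else NULL),
    class = "ygs_scan")
}

as_read_set <- function(x, kmer, default_label) {
  if (inherits(x, "read_kmer_set")) return(x)
  build_read_kmer_set(x, kmer, sex_label = default_label)
}

#' @export
print.ygs_scan <- function(x, ...) {
  cat(sprintf("dual k-mer genome scan (k = %d): %d scaffolds, %.0f bp\n",
              x$index_summary$k, nrow(x$records), x$index_summary$total_bp))
  cat(sprintf("  low quality (excluded from candidacy): %d scaffolds, %.0f bp\n",
              x$n_low_quality, x$bp_low_quality))
  xy <- summarize_candidates(x, "XY")
  zw <- summarize_candidates(x, "ZW")
  cat(sprintf("  XY-side candidates (putative Y): %d scaffolds, %.0f bp\n",
              xy$n_scaffolds, xy$total_bp))
  cat(sprintf("  ZW-side candidates (putative W): %d scaffolds, %.0f bp\n",
              zw$n_scaffolds, zw$total_bp))
  invisible(x)
}

#' Summarise a scan: candidate totals plus the system call
#' @param object A `ygs_scan` object.
#' @param rule A [verdict_rule()] used for the call.
#' @param ... Ignored.
#' @return The `ygs_verdict`, invisibly.
#' @method summary ygs_scan
#' @export
summary.ygs_scan <- function(object, rule = verdict_rule(), ...) {
  v <- call_system(summarize_candidates(object, "XY"),
                   summarize_candidates(object, "ZW"), rule)
  print(object)
  cat("\n")
  print(v)
  invisible(v)
}

#' @method as.data.frame ygs_scan
#' @export
as.data.frame.ygs_scan <- function(x, ...) x$records

#' Histogram pair of the two scan statistics
#'
#' Base-graphics side-by-side histograms of the female-side and male-side
#' unmatched percentages over QC-passing scaffolds. A bimodal left panel
#' with a unimodal right panel indicates an XY system; the mirror image
#' indicates ZW.
#'
#' @param x A `ygs_scan` object.
#' @param bin_width_pct Histogram bin width in percentage points.
#' @param ... Passed to `graphics::barplot()`.
#' @return Invisibly, a list of the two histogram tables.
#' @method plot ygs_scan
#' @export
plot.ygs_scan <- function(x, bin_width_pct = 2, ...) {
  hf <- ygs_histogram(x, "XY", bin_width_pct)
  hm <- ygs_histogram(x, "ZW", bin_width_pct)
  old <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(old))
  for (h in list(list(d = hf, t = "vs female reads (XY-GS)"),
                 list(d = hm, t = "vs male reads (ZW-GS)"))) {
    graphics::barplot(h$d$n_scaffolds,
                      names.arg = h$d$bin_start, main = h$t,
                      xlab = "% single-copy k-mers unmatched",
                      ylab = "scaffolds", ...)
  }
  invisible(list(xy = hf, zw = hm))
}
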