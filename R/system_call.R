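#' Summarise the candidate scaffolds of one side
#'
#' Counts QC-passing candidate scaffolds of the requested side and sums
#' their lengths.
#'
#' @param scan A `ygs_scan` object or a scaffold record data frame with
#'   candidacy flags applied.
#' @param side `"XY"` (Y-linked candidates, flagged against female reads) or
#'   `"ZW"` (W-linked candidates, flagged against male reads).
#' @return An object of class `candidate_summary`: `side`, `n_scaffolds`,
#'   `total_bp`.
#' @export
summarize_candidates <- function(scan, side = c("XY", "ZW")) {
  side <- match.arg(side)
  rec <- if (inherits(scan, "ygs_scan")) scan$records else scan
  stopifnot(is.data.frame(rec))
  flag <- if (side == "XY") rec$is_candidate_xy else rec$is_candidate_zw
  sel <- flag %in% TRUE
  structure(list(side = side,
                 n_scaffolds = sum(sel),
                 total_bp = sum(as.numeric(rec$length_bp[sel]))),
            class = "candidate_summary")
}

#' @export
print.candidate_summary <- function(x, ...) {
  cat(sprintf("%s-side candidates: %d scaffolds, %.0f bp\n",
              x$side, x$n_scaffolds, x$total_bp))
  invisible(x)
}

#' Call the sex-chromosome system from the two candidate summaries
#'
#' Replaces the visual bimodality judgement with an explicit dominance rule:
#' the verdict is XY when the XY-side summary reaches both absolute minima
#' (candidate count and total bp) and dominates the ZW side by the required
#' bp and count ratios; ZW by the mirrored condition; anything else —
#' including ties and two empty sides — is inconclusive.
#'
#' @param xy,zw [summarize_candidates()] results for the two sides (from the
#'   same scan).
#' @param rule A [verdict_rule()] object.
#' @return An object of class `ygs_verdict`: `system` (`"XY"`, `"ZW"` or
#'   `"inconclusive"`), the two summaries, and the rule used.
#' @export
call_system <- function(xy, zw, rule = verdict_rule()) {
  stopifnot(inherits(xy, "candidate_summary"),
            inherits(zw, "candidate_summary"),
            inherits(rule, "verdict_rule"))
  if (xy$side != "XY" || zw$side != "ZW")
    stop("configuration error: pass the XY summary first, the ZW summary second",
         call. = FALSE)
  dominates <- function(a, b) {
    a$n_scaffolds >= rule$min_candidates &&
      a$total_bp >= rule$min_bp &&
      a$total_bp >= rule$bp_ratio * b$total_bp &&
      a$n_scaffolds >= rule$count_ratio * b$n_scaffolds
  }
  xy_wins <- dominates(xy, zw)
  zw_wins <- dominates(zw, xy)
  system <- if (xy_wins && !zw_wins) "XY"
            else if (zw_wins && !xy_wins) "ZW"
            else "inconclusive"
  structure(list(system = system, xy_summary = xy, zw_summary = zw,
                 rule = rule),
            class = "ygs_verdict")
}

#' @export
print.ygs_verdict <- function(x, ...) {
  cat(sprintf("sex-chromosome system call: %s\n", x$system))
  print(x$xy_summary)
  print(x$zw_summary)
  print(x$rule)
  invisible(x)
}

#' Histogram of one scan statistic
#'
#' Bins the QC-passing, non-`NA` per-scaffold unmatched percentages of one
#' side into left-closed right-open bins over `[0, 100]` (the last bin is
#' closed on both ends), reporting scaffold counts and summed lengths per
#' bin. Low-quality scaffolds are excluded, as are scaffolds whose statistic
#' is undefined (no single-copy k-mers).
#'
#' @param scan A `ygs_scan` object or record data frame.
#' @param side `"XY"` (bins `pct_unmatched_female`) or `"ZW"`
#'   (`pct_unmatched_male`).
#' @param bin_width_pct Bin width in percentage points; must divide 100
#'   (default 2).
#' @return Data frame with `bin_start`, `bin_end`, `n_scaffolds`, `total_bp`;
#'   counts over all bins equal the number of QC-passing non-`NA` records.
#' @export
ygs_histogram <- function(scan, side = c("XY", "ZW"), bin_width_pct = 2) {
  side <- match.arg(side)
  rec <- if (inherits(scan, "ygs_scan")) scan$records else scan
  if (bin_width_pct <= 0 || (100 %% bin_width_pct) != 0)
    stop("configuration error: bin width must divide 100", call. = FALSE)
  stat <- if (side == "XY") rec$pct_unmatched_female else rec$pct_unmatched_male
  keep <- rec$qc_pass %in% TRUE & !is.na(stat)
  stat <- stat[keep]
  len <- as.numeric(rec$length_bp[keep])
  starts <- seq(0, 100 - bin_width_pct, by = bin_width_pct)
  idx <- pmin(floor(stat / bin_width_pct), length(starts) - 1) + 1
  data.frame(bin_start = starts,
             bin_end = starts + bin_width_pct,
             n_scaffolds = as.integer(tabulate(idx, nbins = length(starts))),
             total_bp = as.numeric(vapply(seq_along(starts), function(i)
               sum(len[idx == i]), numeric(1))))
}
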