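#' Read sequences from FASTA or FASTQ
#'
#' Autodetects the format from the first record marker (`>` FASTA, `@`
#' FASTQ); gzip compression is detected transparently. FASTA IDs are the
#' first whitespace-delimited token of the header; FASTQ qualities are
#' discarded. Lowercase bases and CRLF line endings are tolerated.
#'
#' @param path Path to a FASTA/FASTQ file, optionally gzip-compressed.
#' @return Named character vector of sequences (names empty-string free for
#'   FASTQ only in pathological headerless cases).
#' @export
read_sequences <- function(path) {
  if (!file.exists(path))
    stop("input error: file not found: ", path, call. = FALSE)
  first <- peek_first_char(path)
  if (is.na(first))
    return(stats::setNames(character(0), character(0)))
  fmt <- if (first == ">") "fasta" else if (first == "@") "fastq" else
    stop("input error: ", path, " is neither FASTA nor FASTQ (starts with '",
         first, "')", call. = FALSE)
  x <- tryCatch(
    Biostrings::readDNAStringSet(path, format = fmt),
    error = function(e) stop("input error: failed to parse ", path, " as ",
                             fmt, ": ", conditionMessage(e), call. = FALSE))
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

peek_first_char <- function(path) {
  con <- gzfile(path, "rt")
  on.exit(close(con))
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L) return(NA_character_)
    line <- sub("\r$", "", line)
    if (nzchar(line)) return(substr(line, 1L, 1L))
  }
}

# Accept a FASTA path or an already-loaded named character vector.
as_assembly_seqs <- function(assembly) {
  if (inherits(assembly, "DNAStringSet")) {
    out <- as.character(assembly)
    names(out) <- sub("\\s.*$", "", names(assembly))
    return(out)
  }
  if (is.character(assembly) && length(assembly) == 1L && file.exists(assembly)) {
    seqs <- read_sequences(assembly)
    if (length(seqs) == 0L)
      stop("input error: empty assembly FASTA: ", assembly, call. = FALSE)
    return(seqs)
  }
  if (is.character(assembly)) {
    if (is.null(names(assembly)) || any(!nzchar(names(assembly))))
      stop("input error: in-memory assembly must be a named character vector",
           call. = FALSE)
    return(assembly)
  }
  stop("input error: assembly must be a FASTA path or named character vector",
       call. = FALSE)
}

read_exclude_ids <- function(exclude_ids) {
  if (is.null(exclude_ids)) return(character(0))
  if (length(exclude_ids) == 1L && file.exists(exclude_ids)) {
    lines <- readLines(exclude_ids, warn = FALSE)
    lines <- sub("\r$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    return(lines)
  }
  as.character(exclude_ids)
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path; `.gz` suffix triggers gzip compression.
#' @param width Line-wrapping width (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, filepath = path, width = width,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Write reads to FASTQ
#'
#' Writes single-end reads with a constant quality string (`I`, Phred 40).
#'
#' @param reads Character vector of read sequences.
#' @param path Output path; `.gz` suffix triggers gzip compression.
#' @param ids Optional read IDs (default `read1 ... readN`).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path, ids = NULL) {
  n <- length(reads)
  if (is.null(ids)) ids <- paste0("read", seq_len(n))
  lines <- character(4L * n)
  lines[seq(1L, by = 4L, length.out = n)] <- paste0("@", ids)
  lines[seq(2L, by = 4L, length.out = n)] <- reads
  lines[seq(3L, by = 4L, length.out = n)] <- "+"
  lines[seq(4L, by = 4L, length.out = n)] <- strrep("I", nchar(reads))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Write the per-scaffold scan table
#'
#' One header line, then one row per retained scaffold with the columns
#' `scaffold_id, length_bp, n_distinct, n_repetitive, n_single_copy,
#' repeat_fraction, pct_absent_both, qc_pass, pct_unmatched_female,
#' pct_unmatched_male, is_candidate_xy, is_candidate_zw`. `NA` is written
#' literally; numeric columns keep full precision so that re-thresholding
#' from the table reproduces the original decisions exactly.
#'
#' @param scan A `ygs_scan` object or its records data frame.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_scan_tsv <- function(scan, path) {
  rec <- if (inherits(scan, "ygs_scan")) scan$records else scan
  stopifnot(is.data.frame(rec))
  out <- rec[scan_tsv_columns()]
  for (col in c("repeat_fraction", "pct_absent_both",
                "pct_unmatched_female", "pct_unmatched_male"))
    out[[col]] <- sprintf_full(out[[col]])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

scan_tsv_columns <- function() {
  c("scaffold_id", "length_bp", "n_distinct", "n_repetitive", "n_single_copy",
    "repeat_fraction", "pct_absent_both", "qc_pass",
    "pct_unmatched_female", "pct_unmatched_male",
    "is_candidate_xy", "is_candidate_zw")
}

# Shortest decimal string that round-trips the double exactly.
sprintf_full <- function(x) {
  out <- sprintf("%.15g", x)
  back <- as.numeric(out)
  hard <- !is.na(x) & back != x
  out[hard] <- sprintf("%.17g", x[hard])
  out[is.na(x)] <- NA_character_
  out
}

#' Read a per-scaffold scan table
#'
#' @param path TSV written by [write_scan_tsv()].
#' @return Data frame of scaffold records.
#' @export
read_scan_tsv <- function(path) {
  if (!file.exists(path))
    stop("input error: file not found: ", path, call. = FALSE)
  rec <- tryCatch(
    utils::read.table(path, header = TRUE, sep = "\t", na.strings = "NA",
                      stringsAsFactors = FALSE, colClasses = c(scaffold_id = "character")),
    error = function(e) stop("input error: malformed scan table ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  missing <- setdiff(scan_tsv_columns(), names(rec))
  if (length(missing))
    stop("input error: scan table ", path, " lacks columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  rec
}

#' Write a machine-readable verdict report
#'
#' JSON with the called system, both candidate summaries, the rule and scan
#' thresholds used, and provenance fields.
#'
#' @param verdict A `ygs_verdict` object from [call_system()].
#' @param path Output path.
#' @param extra Optional named list of provenance fields (input paths, k, ...).
#' @return `path`, invisibly.
#' @export
write_verdict_report <- function(verdict, path, extra = list()) {
  stopifnot(inherits(verdict, "ygs_verdict"))
  payload <- c(list(
    system = verdict$system,
    xy = unclass(verdict$xy_summary),
    zw = unclass(verdict$zw_summary),
    rule = unclass(verdict$rule),
    tool = "ygscan",
    version = as.character(utils::packageVersion("ygscan"))
  ), extra)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Export candidate scaffold sequences to FASTA
#'
#' Writes the sequences of XY-side (or ZW-side) candidate scaffolds, e.g.
#' for downstream PCR primer design.
#'
#' @param scan A `ygs_scan` object that retains sequences
#'   (`ygs_scan(..., keep_sequences = TRUE)`), or a named character vector of
#'   scaffold sequences plus a records data frame via `records`.
#' @param side `"XY"` (Y-linked candidates) or `"ZW"` (W-linked candidates).
#' @param path Output FASTA path.
#' @param records Optional records data frame when `scan` is a plain
#'   sequence vector.
#' @return `path` invisibly; file contains zero records when no candidates.
#' @export
export_candidate_fasta <- function(scan, side = c("XY", "ZW"), path,
                                   records = NULL) {
  side <- match.arg(side)
  if (inherits(scan, "ygs_scan")) {
    records <- scan$records
    seqs <- scan$sequences
    if (is.null(seqs))
      stop("input error: scan was run without keep_sequences = TRUE",
           call. = FALSE)
  } else {
    seqs <- scan
    if (is.null(records))
      stop("input error: records required when passing raw sequences",
           call. = FALSE)
  }
  flag <- if (side == "XY") records$is_candidate_xy else records$is_candidate_zw
  ids <- records$scaffold_id[flag %in% TRUE]
  write_fasta(seqs[ids], path)
}

#' Write a histogram table
#'
#' @param hist Data frame from [ygs_histogram()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_histogram_tsv <- function(hist, path) {
  utils::write.table(hist, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
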