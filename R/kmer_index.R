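#' Canonical encoding of fixed-length DNA words
#'
#' Encodes each k-base window as the lexicographically smaller of the window
#' and its reverse complement under the base order A=0, C=1, G=2, T=3, most
#' significant base first. Canonicalisation collapses the strand ambiguity of
#' shotgun reads, which is what makes assembly-versus-read k-mer comparison
#' well defined.
#'
#' Codes are returned as doubles and are exact for `k <= 26`; internally all
#' set operations use 64-bit integers, so larger `k` never loses precision
#' inside a scan.
#'
#' @param window Character vector of DNA words, each exactly `k` bases.
#' @param k Word length.
#' @return Numeric vector of codes in `[0, 4^k)`; `NA` for windows containing
#'   any character outside ACGT (case-insensitive).
#' @examples
#' canonical_encode("ACG", 3)   # 6: ACG=6 beats its reverse complement CGT=27
#' canonical_encode("ACGT", 4)  # 27: reverse-complement palindrome
#' canonical_encode("ACN", 3)   # NA
#' @export
canonical_encode <- function(window, k) {
  k <- as.integer(k)
  if (is.na(k) || k < 2L || k > 31L)
    stop("configuration error: k must be in [2, 31]", call. = FALSE)
  cpp_encode_windows(as.character(window), k)
}

#' Decode a canonical k-mer code back to its DNA word
#'
#' @param code Numeric vector of codes as produced by [canonical_encode()].
#' @param k Word length.
#' @return Character vector of k-base words (the canonical representative).
#' @export
decode_kmer <- function(code, k) {
  k <- as.integer(k)
  cpp_decode_codes(as.numeric(code), k)
}

#' Decompose a sequence into canonical k-mer codes
#'
#' Slides a k-base window over the sequence and emits one code per valid
#' window; windows containing non-ACGT characters (e.g. N-gap bases) are
#' skipped individually, so an internal gap does not discard the whole
#' scaffold. Lowercase is accepted.
#'
#' @param seq A single DNA string.
#' @param k Word length.
#' @return Numeric vector of codes in window order (possibly empty).
#' @examples
#' sequence_kmers("AAAACCC", 3)  # 5 codes; AAA appears twice
#' sequence_kmers("AC", 3)       # empty
#' @export
sequence_kmers <- function(seq, k) {
  stopifnot(length(seq) == 1L)
  k <- as.integer(k)
  if (is.na(k) || k < 2L || k > 31L)
    stop("configuration error: k must be in [2, 31]", call. = FALSE)
  cpp_sequence_kmers(as.character(seq), k)
}

#' Build the assembly k-mer index
#'
#' Retains scaffolds of at least `min_scaffold_len` bp that are not in the
#' exclusion list, counts every valid canonical k-mer window across all
#' retained scaffolds, and partitions the distinct k-mers into a single-copy
#' set (total occurrence count exactly 1) and a repetitive set (count > 1).
#' Occurrences are counted per window, so a k-mer repeated within one
#' scaffold — or equal to its own reverse complement's other occurrence — is
#' repetitive. Repetitive k-mers are exactly the multi-mapping sequences
#' (transposons, satellites) that would otherwise create false sharing
#' between a sex-limited chromosome and the autosomes.
#'
#' @param assembly Path to a FASTA file (gzip accepted), or a named character
#'   vector of scaffold sequences.
#' @param params A [kmer_params()] object.
#' @param exclude_ids Optional character vector of scaffold IDs to drop
#'   (e.g. externally identified contaminants), or a path to a plain-text
#'   file with one ID per line (`#` comment lines ignored).
#' @return An object of class `assembly_index` with elements `single_copy`
#'   and `repetitive` (opaque k-mer set handles), `scaffold_lengths` (named
#'   integer vector over retained scaffolds), `k`, and counts of excluded /
#'   too-short scaffolds.
#' @export
build_assembly_index <- function(assembly, params = kmer_params(),
                                 exclude_ids = NULL) {
  stopifnot(inherits(params, "kmer_params"))
  seqs <- as_assembly_seqs(assembly)
  if (length(seqs) == 0L)
    stop("input error: assembly contains no sequences", call. = FALSE)
  ids <- names(seqs)
  if (anyDuplicated(ids))
    stop("input error: duplicate scaffold IDs in assembly: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  excl <- read_exclude_ids(exclude_ids)
  n_excluded <- sum(ids %in% excl)
  seqs <- seqs[!(ids %in% excl)]
  lens <- nchar(seqs)
  n_short <- sum(lens < params$min_scaffold_len)
  seqs <- seqs[lens >= params$min_scaffold_len]
  if (length(seqs) == 0L)
    stop("input error: no scaffold of length >= min_scaffold_len remains",
         call. = FALSE)
  counter <- cpp_counter_new(params$k)
  cpp_counter_add(counter, unname(seqs))
  parts <- cpp_counter_split(counter)
  structure(list(single_copy = new_kmer_set(parts$single_copy, params$k, "assembly single-copy"),
                 repetitive = new_kmer_set(parts$repetitive, params$k, "assembly repetitive"),
                 scaffold_lengths = stats::setNames(nchar(seqs), names(seqs)),
                 k = params$k,
                 n_excluded = n_excluded,
                 n_too_short = n_short),
            class = "assembly_index")
}

#' @export
print.assembly_index <- function(x, ...) {
  cat(sprintf("assembly k-mer index (k = %d): %d retained scaffolds, %.0f bp\n",
              x$k, length(x$scaffold_lengths), sum(as.numeric(x$scaffold_lengths))))
  cat(sprintf("  single-copy k-mers: %.0f   repetitive k-mers: %.0f\n",
              kmer_set_size(x$single_copy), kmer_set_size(x$repetitive)))
  if (x$n_excluded + x$n_too_short > 0)
    cat(sprintf("  dropped: %d excluded by ID, %d below length cutoff\n",
                x$n_excluded, x$n_too_short))
  invisible(x)
}

#' Build one sex's read k-mer set
#'
#' Decomposes all reads of one sex into canonical k-mers and keeps those
#' whose total multiplicity across all input reads is at least
#' `min_read_count`. Multiple files (e.g. the two mates of a paired run) are
#' concatenated logically; quality strings are ignored (reads are assumed
#' pre-trimmed upstream).
#'
#' @param reads Character vector of FASTQ/FASTA paths (gzip accepted), or
#'   a character vector of raw read sequences (anything that does not name
#'   an existing file is treated as a sequence).
#' @param params A [kmer_params()] object.
#' @param sex_label Free-text label, conventionally `"male"` or `"female"`.
#' @return An object of class `read_kmer_set` with the opaque set handle,
#'   `k`, `sex_label`, the member count `n_members`, and the number of reads
#'   consumed.
#' @export
build_read_kmer_set <- function(reads, params = kmer_params(),
                                sex_label = "unknown") {
  stopifnot(inherits(params, "kmer_params"))
  counter <- cpp_counter_new(params$k)
  n_reads <- 0L
  if (is.character(reads) && length(reads) > 0 && all(file.exists(reads))) {
    for (path in reads) {
      rs <- read_sequences(path)
      n_reads <- n_reads + length(rs)
      cpp_counter_add(counter, unname(rs))
    }
  } else if (is.character(reads)) {
    n_reads <- length(reads)
    cpp_counter_add(counter, unname(reads))
  } else {
    stop("input error: reads must be file paths or a character vector of sequences",
         call. = FALSE)
  }
  if (n_reads == 0L)
    stop("input error: no readable read records supplied", call. = FALSE)
  set <- cpp_counter_to_set(counter, params$min_read_count)
  structure(list(set = new_kmer_set(set, params$k, sex_label),
                 k = params$k,
                 sex_label = sex_label,
                 n_members = cpp_set_size(set),
                 n_reads = n_reads),
            class = "read_kmer_set")
}

#' @export
print.read_kmer_set <- function(x, ...) {
  cat(sprintf("read k-mer set '%s' (k = %d): %.0f members from %d reads\n",
              x$sex_label, x$k, x$n_members, x$n_reads))
  invisible(x)
}

# --- opaque k-mer set handle ------------------------------------------------

new_kmer_set <- function(ptr, k, label) {
  structure(list(ptr = ptr, k = k, label = label), class = "kmer_set")
}

#' Size of a k-mer set
#' @param set A `kmer_set` handle (e.g. `index$single_copy`).
#' @return Number of member k-mers.
#' @export
kmer_set_size <- function(set) {
  if (inherits(set, "read_kmer_set")) set <- set$set
  stopifnot(inherits(set, "kmer_set"))
  cpp_set_size(set$ptr)
}

#' Membership test on a k-mer set
#' @param set A `kmer_set` handle or a `read_kmer_set`.
#' @param codes Numeric vector of canonical codes ([canonical_encode()]).
#' @return Logical vector.
#' @export
kmer_set_contains <- function(set, codes) {
  if (inherits(set, "read_kmer_set")) set <- set$set
  stopifnot(inherits(set, "kmer_set"))
  cpp_set_contains(set$ptr, as.numeric(codes))
}

#' Enumerate a k-mer set
#'
#' Returns all member codes, sorted ascending. Intended for small sets
#' (toy problems, tests); a genome-scale set can be very large.
#' @inheritParams kmer_set_contains
#' @return Numeric vector of codes.
#' @export
kmer_set_codes <- function(set) {
  if (inherits(set, "read_kmer_set")) set <- set$set
  stopifnot(inherits(set, "kmer_set"))
  cpp_set_codes(set$ptr)
}

#' @export
print.kmer_set <- function(x, ...) {
  cat(sprintf("k-mer set '%s' (k = %d): %.0f members\n",
              x$label, x$k, cpp_set_size(x$ptr)))
  invisible(x)
}
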