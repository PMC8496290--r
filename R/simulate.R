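#' Specification of a synthetic sex-chromosome genome
#'
#' Describes a diploid genome with autosomes, a sex chromosome shared by
#' both sexes (X or Z), and a sex-limited chromosome (Y or W) made of unique
#' sequence interleaved with repeat-family monomers that also occur on the
#' autosomes. Defaults emulate a draft-genome study sequenced to ~20x per
#' sex with 100 bp reads and a small substitution-error rate.
#'
#' @param system `"XY"` (male-heterogametic, sex-limited chromosome is Y) or
#'   `"ZW"` (female-heterogametic, sex-limited chromosome is W).
#' @param autosome_lengths Lengths (bp) of the autosomes.
#' @param x_length Length (bp) of the shared sex chromosome (X or Z).
#' @param y_length Length (bp) of the sex-limited chromosome (Y or W).
#' @param y_unique_fraction Fraction of the sex-limited chromosome built
#'   from sequence absent elsewhere in the genome; the remainder is repeat
#'   copies shared with the autosomes.
#' @param n_repeat_families Number of distinct repeat monomer families.
#' @param repeat_unit_length Length (bp) of each repeat monomer.
#' @param scaffold_length Length (bp) into which chromosomes are fragmented
#'   to mimic a draft assembly (the last piece of a chromosome may be
#'   shorter).
#' @param read_length Read length (bp).
#' @param depth Expected per-base sequencing depth per sex.
#' @param error_rate Per-base substitution probability.
#' @param seed Integer seed; every simulator output is deterministic given
#'   the spec.
#' @return An object of class `sim_spec`.
#' @export
sim_spec <- function(system = c("XY", "ZW"),
                     autosome_lengths = c(800000L, 600000L),
                     x_length = 400000L,
                     y_length = 200000L,
                     y_unique_fraction = 0.8,
                     n_repeat_families = 5L,
                     repeat_unit_length = 2000L,
                     scaffold_length = 20000L,
                     read_length = 100L,
                     depth = 20,
                     error_rate = 0.005,
                     seed = 1L) {
  system <- match.arg(system)
  spec <- list(system = system,
               autosome_lengths = as.integer(autosome_lengths),
               x_length = as.integer(x_length),
               y_length = as.integer(y_length),
               y_unique_fraction = as.numeric(y_unique_fraction),
               n_repeat_families = as.integer(n_repeat_families),
               repeat_unit_length = as.integer(repeat_unit_length),
               scaffold_length = as.integer(scaffold_length),
               read_length = as.integer(read_length),
               depth = as.numeric(depth),
               error_rate = as.numeric(error_rate),
               seed = as.integer(seed))
  if (spec$y_unique_fraction < 0 || spec$y_unique_fraction > 1)
    stop("configuration error: y_unique_fraction must lie in [0, 1]",
         call. = FALSE)
  if (any(c(spec$autosome_lengths, spec$x_length, spec$y_length) < spec$read_length))
    stop("configuration error: every chromosome must be at least read_length",
         call. = FALSE)
  if (spec$depth <= 0)
    stop("configuration error: depth must be positive", call. = FALSE)
  if (spec$error_rate < 0 || spec$error_rate >= 0.25)
    stop("configuration error: error_rate must lie in [0, 0.25)", call. = FALSE)
  if (spec$scaffold_length < 1L || spec$read_length < 1L)
    stop("configuration error: lengths must be positive", call. = FALSE)
  structure(spec, class = "sim_spec")
}

#' @export
print.sim_spec <- function(x, ...) {
  cat(sprintf("synthetic %s genome: autosomes %s bp, %s %d bp, %s %d bp (%.0f%% unique)\n",
              x$system, paste(x$autosome_lengths, collapse = "+"),
              if (x$system == "XY") "X" else "Z", x$x_length,
              if (x$system == "XY") "Y" else "W", x$y_length,
              100 * x$y_unique_fraction))
  cat(sprintf("  %d repeat families x %d bp; scaffolds %d bp; reads %d bp at %gx, error %g; seed %d\n",
              x$n_repeat_families, x$repeat_unit_length, x$scaffold_length,
              x$read_length, x$depth, x$error_rate, x$seed))
  invisible(x)
}

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Simulate a sex-chromosome genome and its draft-assembly scaffolds
#'
#' Builds the chromosomes described by the spec, fragments the heterogametic
#' individual's chromosomes into scaffolds (the "assembly"), and returns the
#' two sexes' full genome sequence sets plus a truth table. Autosomes and
#' the shared chromosome occur in both sexes; the sex-limited chromosome is
#' present only in the heterogametic sex. Repeat monomers are copied onto
#' the autosomes and interleaved into the sex-limited chromosome, so their
#' k-mers are repetitive in the assembly, while the sex-limited chromosome's
#' unique portion has no counterpart in the homogametic sex.
#'
#' @param spec A [sim_spec()] object.
#' @return List with `assembly` (named character vector of scaffolds),
#'   `male_genome`, `female_genome` (named chromosome sequence vectors),
#'   `truth` (data frame: `scaffold_id`, `chromosome`, `repeat_fraction`),
#'   and `spec`. Fully deterministic given `spec$seed`.
#' @export
simulate_genome <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed)
  families <- vapply(seq_len(spec$n_repeat_families),
                     function(i) rand_dna(spec$repeat_unit_length), character(1))

  # autosomes: random background with implanted repeat copies
  autosomes <- list()
  for (i in seq_along(spec$autosome_lengths)) {
    L <- spec$autosome_lengths[i]
    seq <- rand_dna(L)
    mask <- logical(L)
    for (fam in families) {
      # a few copies of every family per autosome keeps them repetitive
      for (cp in seq_len(2L)) {
        if (L <= spec$repeat_unit_length) next
        pos <- sample.int(L - spec$repeat_unit_length + 1L, 1L)
        substr(seq, pos, pos + spec$repeat_unit_length - 1L) <- fam
        mask[pos:(pos + spec$repeat_unit_length - 1L)] <- TRUE
      }
    }
    autosomes[[paste0("A", i)]] <- list(seq = seq, mask = mask)
  }

  shared_name <- if (spec$system == "XY") "X" else "Z"
  limited_name <- if (spec$system == "XY") "Y" else "W"
  shared <- list(seq = rand_dna(spec$x_length), mask = logical(spec$x_length))

  # sex-limited chromosome: unique blocks interleaved with repeat units
  target_repeat <- round((1 - spec$y_unique_fraction) * spec$y_length)
  n_units <- target_repeat %/% spec$repeat_unit_length
  unit_lens <- rep(spec$repeat_unit_length, n_units)
  partial <- target_repeat - sum(unit_lens)
  if (partial > 0) unit_lens <- c(unit_lens, partial)
  unique_total <- spec$y_length - sum(unit_lens)
  n_unique_blocks <- length(unit_lens) + 1L
  ub <- rep(unique_total %/% n_unique_blocks, n_unique_blocks)
  ub[1] <- ub[1] + unique_total - sum(ub)
  blocks <- character(0); bmask <- list()
  for (j in seq_len(n_unique_blocks)) {
    if (ub[j] > 0) {
      blocks <- c(blocks, rand_dna(ub[j]))
      bmask <- c(bmask, list(rep(FALSE, ub[j])))
    }
    if (j <= length(unit_lens)) {
      fam <- families[((j - 1L) %% spec$n_repeat_families) + 1L]
      blocks <- c(blocks, substr(fam, 1L, unit_lens[j]))
      bmask <- c(bmask, list(rep(TRUE, unit_lens[j])))
    }
  }
  limited <- list(seq = paste(blocks, collapse = ""), mask = unlist(bmask))
  stopifnot(nchar(limited$seq) == spec$y_length)

  chroms <- c(autosomes, stats::setNames(list(shared), shared_name),
              stats::setNames(list(limited), limited_name))

  # fragment all chromosomes of the heterogametic individual into scaffolds
  assembly <- character(0)
  truth <- list()
  for (nm in names(chroms)) {
    seq <- chroms[[nm]]$seq
    mask <- chroms[[nm]]$mask
    L <- nchar(seq)
    starts <- seq.int(1L, L, by = spec$scaffold_length)
    ends <- pmin(starts + spec$scaffold_length - 1L, L)
    ids <- sprintf("%s_scf%04d", nm, seq_along(starts))
    pieces <- substring(seq, starts, ends)
    names(pieces) <- ids
    assembly <- c(assembly, pieces)
    truth[[nm]] <- data.frame(
      scaffold_id = ids,
      chromosome = nm,
      repeat_fraction = vapply(seq_along(starts), function(i)
        mean(mask[starts[i]:ends[i]]), numeric(1)),
      stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL

  chrom_seqs <- vapply(chroms, `[[`, character(1), "seq")
  both <- chrom_seqs[c(names(autosomes), shared_name)]
  het <- chrom_seqs
  if (spec$system == "XY") {
    male_genome <- het; female_genome <- both
  } else {
    male_genome <- both; female_genome <- het
  }
  list(assembly = assembly, male_genome = male_genome,
       female_genome = female_genome, truth = truth, spec = spec)
}

#' Simulate error-prone single-end short reads
#'
#' Draws reads of `read_length` uniformly over positions and strands of the
#' supplied genome to reach the expected per-base depth, then applies
#' per-base substitutions at `error_rate` (each error replaces the base with
#' a uniformly chosen different base). Deterministic given `seed`.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param spec A [sim_spec()] object (supplies read length, depth, error
#'   rate).
#' @param seed Seed for this read set (default `spec$seed`).
#' @return Character vector of read sequences, length
#'   `round(depth * total_bp / read_length)`.
#' @export
simulate_reads <- function(genome, spec, seed = spec$seed) {
  stopifnot(inherits(spec, "sim_spec"))
  lens <- nchar(genome)
  if (any(lens < spec$read_length))
    stop("configuration error: genome sequence shorter than read_length",
         call. = FALSE)
  set.seed(seed)
  rl <- spec$read_length
  total_bp <- sum(as.numeric(lens))
  n_reads <- round(spec$depth * total_bp / rl)
  chrom <- sample.int(length(genome), n_reads, replace = TRUE,
                      prob = lens / total_bp)
  start <- 1L + floor(stats::runif(n_reads) * (lens[chrom] - rl + 1L))
  minus <- stats::runif(n_reads) < 0.5
  reads <- character(n_reads)
  for (ci in seq_along(genome)) {
    sel <- chrom == ci
    if (any(sel))
      reads[sel] <- substring(genome[[ci]], start[sel], start[sel] + rl - 1L)
  }
  if (any(minus)) reads[minus] <- revcomp(reads[minus])
  if (spec$error_rate > 0) {
    n_err <- stats::rbinom(n_reads, rl, spec$error_rate)
    hit <- which(n_err > 0)
    if (length(hit)) {
      read_idx <- rep(hit, n_err[hit])
      pos <- sample.int(rl, length(read_idx), replace = TRUE)
      cur <- substring(reads[read_idx], pos, pos)
      bases <- c("A", "C", "G", "T")
      cur_i <- match(cur, bases)
      off <- sample.int(3L, length(read_idx), replace = TRUE)
      repl <- bases[((cur_i - 1L + off) %% 4L) + 1L]
      reads <- cpp_apply_substitutions(reads, read_idx, pos, repl)
    }
  }
  reads
}

#' Simulate a complete dataset: assembly, per-sex reads, truth table
#'
#' Convenience wrapper: genome from `spec$seed`, male reads from
#' `spec$seed + 1`, female reads from `spec$seed + 2`. Optionally writes
#' `assembly.fasta`, `male.fastq.gz`, `female.fastq.gz` and `truth.tsv`
#' into a directory.
#'
#' @param spec A [sim_spec()] object.
#' @param dir Optional output directory (created if needed).
#' @return List with `assembly`, `male_reads`, `female_reads`, `truth`,
#'   `spec`, and (when `dir` is given) `paths`.
#' @export
simulate_ygs_dataset <- function(spec, dir = NULL) {
  g <- simulate_genome(spec)
  male_reads <- simulate_reads(g$male_genome, spec, seed = spec$seed + 1L)
  female_reads <- simulate_reads(g$female_genome, spec, seed = spec$seed + 2L)
  out <- list(assembly = g$assembly, male_reads = male_reads,
              female_reads = female_reads, truth = g$truth, spec = spec)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(assembly = file.path(dir, "assembly.fasta"),
                  male = file.path(dir, "male.fastq.gz"),
                  female = file.path(dir, "female.fastq.gz"),
                  truth = file.path(dir, "truth.tsv"))
    write_fasta(g$assembly, paths$assembly)
    write_fastq(male_reads, paths$male)
    write_fastq(female_reads, paths$female)
    utils::write.table(g$truth, paths$truth, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    out$paths <- paths
  }
  out
}

#' Evaluate scan recovery against simulation truth
#'
#' Compares the scan's candidate flags with the simulator's truth labels:
#' sensitivity is the fraction of sex-limited (Y or W) scaffolds with at
#' least half their bases unique-derived that are flagged candidates on the
#' correct side; the false-positive rate is the fraction of autosomal and
#' shared-chromosome scaffolds flagged on that side.
#'
#' @param scan A `ygs_scan` object run on the simulated assembly and reads.
#' @param truth Truth data frame from [simulate_genome()].
#' @param verdict Optional `ygs_verdict` to check against the truth system.
#' @return List: `system_truth`, `system_called`, `verdict_correct`,
#'   `sensitivity`, `fpr`, and the evaluation counts.
#' @export
evaluate_recovery <- function(scan, truth, verdict = NULL) {
  rec <- if (inherits(scan, "ygs_scan")) scan$records else scan
  if (!all(rec$scaffold_id %in% truth$scaffold_id))
    stop("input error: scan contains scaffold IDs absent from the truth table",
         call. = FALSE)
  tr <- truth[match(rec$scaffold_id, truth$scaffold_id), ]
  system_truth <- if (any(tr$chromosome == "Y")) "XY"
                  else if (any(tr$chromosome == "W")) "ZW"
                  else stop("input error: truth table has no sex-limited scaffolds",
                            call. = FALSE)
  flag <- if (system_truth == "XY") rec$is_candidate_xy else rec$is_candidate_zw
  limited <- tr$chromosome %in% c("Y", "W")
  eligible <- limited & tr$repeat_fraction <= 0.5
  background <- !limited
  sens <- if (any(eligible)) mean(flag[eligible] %in% TRUE) else NA_real_
  fpr <- if (any(background)) mean(flag[background] %in% TRUE) else NA_real_
  out <- list(system_truth = system_truth,
              system_called = if (!is.null(verdict)) verdict$system else NA_character_,
              verdict_correct = if (!is.null(verdict))
                identical(verdict$system, system_truth) else NA,
              sensitivity = sens,
              fpr = fpr,
              n_sex_limited_eval = sum(eligible),
              n_background = sum(background))
  class(out) <- "ygs_recovery"
  out
}

#' @export
print.ygs_recovery <- function(x, ...) {
  cat(sprintf("recovery vs truth (%s system): called %s (%s)\n",
              x$system_truth, x$system_called,
              if (isTRUE(x$verdict_correct)) "correct" else "incorrect or unchecked"))
  cat(sprintf("  sensitivity %.3f on %d sex-limited scaffolds; FPR %.4f on %d background scaffolds\n",
              x$sensitivity, x$n_sex_limited_eval, x$fpr, x$n_background))
  invisible(x)
}
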