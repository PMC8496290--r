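test_that("canonical encoding matches hand-evaluated codes and rejects invalid windows", {
  expect_equal(canonical_encode("ACG", 3), 6)        # ACG=6 < revcomp CGT=27
  expect_equal(canonical_encode("ACGT", 4), 27)      # rc-palindrome fixed point
  expect_true(is.na(canonical_encode("ACN", 3)))
  expect_equal(canonical_encode("acg", 3), 6)        # lowercase equivalent
  expect_error(canonical_encode("ACGT", 3), "length")
  expect_error(canonical_encode("AC", 1), "k must be")
  expect_error(canonical_encode("AC", 32), "k must be")
})

test_that("canonical encoding is idempotent and strand-invariant on random windows", {
  set.seed(11)
  for (k in c(3L, 5L, 16L, 26L)) {
    w <- vapply(1:50, function(i)
      paste(sample(c("A", "C", "G", "T"), k, replace = TRUE), collapse = ""),
      character(1))
    code <- canonical_encode(w, k)
    expect_true(all(code >= 0 & code < 4^k))
    # decode/encode round-trip is a fixed point
    expect_equal(canonical_encode(decode_kmer(code, k), k), code)
    # reverse-complementing the window leaves the code unchanged
    expect_equal(canonical_encode(oracle_revcomp(w), k), code)
    # agrees with string-comparison canonicalisation
    expect_equal(decode_kmer(code, k), pmin(w, oracle_revcomp(w)))
  }
})

test_that("sequence decomposition emits one code per valid window and skips invalid ones", {
  codes <- sequence_kmers("AAAACCC", 3)
  expect_length(codes, 5)
  expect_setequal(decode_kmer(unique(codes), 3), c("AAA", "AAC", "ACC", "CCC"))
  expect_equal(sum(codes == canonical_encode("AAA", 3)), 2)
  expect_length(sequence_kmers("AC", 3), 0)
  expect_length(sequence_kmers("ACNGT", 3), 0)   # every window contains N
  # N invalidates only the windows containing it
  expect_equal(decode_kmer(sequence_kmers("ACGNACG", 3), 3),
               decode_kmer(rep(canonical_encode("ACG", 3), 2), 3))
  expect_equal(sequence_kmers("aaaaccc", 3), sequence_kmers("AAAACCC", 3))
})

test_that("assembly index partitions distinct k-mers into single-copy and repetitive", {
  p <- kmer_params(k = 3, min_scaffold_len = 3)
  idx <- build_assembly_index(c(s1 = "AAAACCC"), p)
  expect_setequal(decode_kmer(kmer_set_codes(idx$single_copy), 3),
                  c("AAC", "ACC", "CCC"))
  expect_setequal(decode_kmer(kmer_set_codes(idx$repetitive), 3), "AAA")

  # AAC occurs in both scaffolds (TAACT contains AAC via canonicalisation)
  idx2 <- build_assembly_index(c(s1 = "AAAACCC", s2 = "TAACT"), p)
  single2 <- decode_kmer(kmer_set_codes(idx2$single_copy), 3)
  repet2 <- decode_kmer(kmer_set_codes(idx2$repetitive), 3)
  expect_setequal(repet2, c("AAA", "AAC"))
  expect_setequal(single2,
                  pmin(c("ACC", "CCC", "TAA", "ACT"),
                       oracle_revcomp(c("ACC", "CCC", "TAA", "ACT"))))
  expect_equal(idx2$scaffold_lengths, c(s1 = 7L, s2 = 5L))
})

test_that("assembly index validates input and applies exclusions and length cutoff", {
  p <- kmer_params(k = 3, min_scaffold_len = 5)
  expect_error(build_assembly_index(character(0), p), "input error")
  expect_error(build_assembly_index(c(a = "ACGTACG", a = "ACGTACG"), p),
               "duplicate")
  # too-short scaffolds are dropped before counting
  idx <- build_assembly_index(c(long = "AAAACCC", tiny = "ACGT"), p)
  expect_equal(names(idx$scaffold_lengths), "long")
  expect_equal(idx$n_too_short, 1L)
  # excluded scaffold contributes no k-mers
  idx2 <- build_assembly_index(c(s1 = "AAAACCC", s2 = "TGGGTGG"), p,
                               exclude_ids = "s2")
  expect_equal(names(idx2$scaffold_lengths), "s1")
  expect_false(any(kmer_set_contains(idx2$single_copy, canonical_encode("TGG", 3))))
  expect_false(any(kmer_set_contains(idx2$repetitive, canonical_encode("TGG", 3))))
  # exclusion list file with comments
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# contaminants", "s2"), f)
  idx3 <- build_assembly_index(c(s1 = "AAAACCC", s2 = "TTTTTTT"), p,
                               exclude_ids = f)
  expect_equal(names(idx3$scaffold_lengths), "s1")
  expect_error(build_assembly_index(c(tiny = "ACGT"), p), "min_scaffold_len")
})

test_that("index partition matches the string-map oracle on random assemblies", {
  set.seed(21)
  for (k in c(3L, 5L)) {
    for (rep in 1:5) {
      toy <- random_toy(k)
      p <- kmer_params(k = k, min_scaffold_len = k)
      idx <- build_assembly_index(toy$assembly, p)
      tab <- table(unlist(lapply(toy$assembly, oracle_kmers, k = k)))
      expect_setequal(decode_kmer(kmer_set_codes(idx$single_copy), k),
                      names(tab)[tab == 1])
      expect_setequal(decode_kmer(kmer_set_codes(idx$repetitive), k),
                      names(tab)[tab > 1])
      expect_equal(kmer_set_size(idx$single_copy) + kmer_set_size(idx$repetitive),
                   length(tab))
    }
  }
})

test_that("read k-mer set applies the multiplicity threshold over all input reads", {
  p <- kmer_params(k = 3, min_read_count = 2, min_scaffold_len = 3)
  s <- build_read_kmer_set("AAAA", p, "m")   # AAA occurs twice in one read
  expect_equal(decode_kmer(kmer_set_codes(s), 3), "AAA")
  expect_equal(kmer_set_size(build_read_kmer_set("AACG", p, "m")), 0)
  # multiplicity accumulates across reads and across files
  s2 <- build_read_kmer_set(c("AACG", "AACG"), p, "m")
  expect_setequal(decode_kmer(kmer_set_codes(s2), 3),
                  unique(pmin(c("AAC", "ACG"), oracle_revcomp(c("AAC", "ACG")))))
  expect_error(build_read_kmer_set(character(0), p, "m"), "input error")
})

test_that("read sets are monotone in the reads and strand-invariant", {
  set.seed(31)
  p <- kmer_params(k = 5, min_read_count = 2, min_scaffold_len = 5)
  for (rep in 1:5) {
    toy <- random_toy(5L)
    r_small <- toy$male
    r_big <- c(toy$male, toy$female)
    small <- kmer_set_codes(build_read_kmer_set(r_small, p, "a"))
    big <- kmer_set_codes(build_read_kmer_set(r_big, p, "a"))
    expect_true(all(small %in% big))
    # reverse-complementing every read leaves the set unchanged
    flipped <- kmer_set_codes(build_read_kmer_set(oracle_revcomp(r_small), p, "a"))
    expect_equal(small, flipped)
    # matches the oracle
    expect_setequal(decode_kmer(small, 5),
                    oracle_read_set(r_small, 5, 2))
  }
})

test_that("plain and gzip-compressed read files yield identical k-mer sets", {
  set.seed(41)
  toy <- random_toy(5L)
  p <- kmer_params(k = 5, min_read_count = 1, min_scaffold_len = 5)
  plain <- withr::local_tempfile(fileext = ".fastq")
  gz <- withr::local_tempfile(fileext = ".fastq.gz")
  write_fastq(toy$male, plain)
  write_fastq(toy$male, gz)
  s1 <- build_read_kmer_set(plain, p, "m")
  s2 <- build_read_kmer_set(gz, p, "m")
  expect_equal(kmer_set_codes(s1), kmer_set_codes(s2))
  expect_gt(kmer_set_size(s1), 0)
})
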