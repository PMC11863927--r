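fix <- make_test_refs(te_len = 800, scg_len = 900, n_diag = 3)
refs_small <- fix$refs

test_that("trim_reads truncates from the 3' end and drops short reads", {
  reads <- c(a = paste(rep("ACGT", 40), collapse = ""),  # 160 bp
             b = strrep("A", 100),
             c = strrep("G", 30))
  out <- trim_reads(reads, target_length = 100, min_keep = 50)
  expect_named(out, c("a", "b"))
  expect_identical(unname(out[["a"]]), substr(reads[["a"]], 1, 100))
  expect_identical(out[["b"]], reads[["b"]])

  ## counting oracle on random lengths
  set.seed(5)
  lens <- sample(20:150, 200, replace = TRUE)
  rnd <- vapply(lens, function(L) rand_seq(L), "")
  kept <- trim_reads(rnd, 100, 50)
  expect_length(kept, sum(lens >= 50))
  expect_true(all(nchar(kept) <= 100))

  expect_error(trim_reads(rnd, 10, 50), "min_keep")
  expect_identical(trim_reads(character(0), 100, 50), character(0))
})

test_that("error-free synthetic reads align at their truth positions", {
  spec <- pool_spec("melanogaster", n_individuals = 10, copy_number_mean = 4,
                    depth = 20, read_length = 50, error_rate = 0, seed = 41)
  pool <- simulate_pool(spec, refs_small)
  expect_gt(length(pool$reads), 1000)
  aln <- align_reads(pool$reads, refs_small, species = "melanogaster",
                     seed_length = 20)
  tr <- pool$truth$reads
  m <- match(tr$id, aln$id)
  expect_identical(aln$pos[m], tr$start)
  expect_identical(aln$ref[m], tr$ref)
})

test_that("a full-penetrance deletion leaves zero coverage inside the interval", {
  spec <- pool_spec("melanogaster", n_individuals = 10, copy_number_mean = 5,
                    deletion_fraction = 1, deletion_interval = c(300, 500),
                    depth = 20, read_length = 50, error_rate = 0, seed = 42)
  pool <- simulate_pool(spec, refs_small)
  aln <- align_reads(pool$reads, refs_small, species = "melanogaster")
  counts <- pileup(aln, refs_small, species = "melanogaster")
  inside <- counts$ref == refs_small$te_name &
    counts$pos >= 300 & counts$pos <= 500
  expect_true(all(counts$cov[inside] == 0))
  expect_gt(mean(counts$cov[counts$ref == refs_small$te_name & !inside &
                              counts$pos > 50 & counts$pos < 750]), 0)
})

test_that("pileup tallies bases and handles edge cases", {
  aln <- structure(
    data.frame(id = "r1", ref = refs_small$te_name, pos = 1L,
               seq = "ACGT", mismatches = 0L),
    class = c("alignments", "data.frame"))
  counts <- pileup(aln, refs_small, species = "melanogaster")
  te <- counts[counts$ref == refs_small$te_name, ]
  expect_identical(te$cov[1:4], rep(1L, 4))
  expect_identical(c(te$A[1], te$C[2], te$G[3], te$T[4]), rep(1L, 4))
  expect_true(all(te$cov[-(1:4)] == 0))

  empty <- pileup(aln[0, ], refs_small, species = "melanogaster")
  expect_true(all(empty$cov == 0))

  ## N bases count neither allele nor coverage
  aln$seq <- "ANGT"
  counts_n <- pileup(aln, refs_small, species = "melanogaster")
  te_n <- counts_n[counts_n$ref == refs_small$te_name, ]
  expect_identical(te_n$cov[2], 0L)

  ## overhanging alignment rejected with warning
  aln_bad <- aln
  aln_bad$pos <- nchar(refs_small$te_sequence)
  expect_warning(pileup(aln_bad, refs_small, species = "melanogaster"),
                 "beyond")
})

test_that("error-free pileup allele fractions equal read-level truth exactly", {
  spec <- pool_spec("melanogaster", n_individuals = 20, copy_number_mean = 5,
                    allele_profile = list("400" = c(A = 0.5, G = 0.5)),
                    depth = 30, read_length = 50, error_rate = 0, seed = 43)
  pool <- simulate_pool(spec, refs_small)
  aln <- align_reads(pool$reads, refs_small, species = "melanogaster")
  counts <- pileup(aln, refs_small, species = "melanogaster")
  at <- counts[counts$ref == refs_small$te_name & counts$pos == 400, ]

  ## oracle: tally copy alleles of the TE reads covering site 400
  tr <- pool$truth$reads
  cover <- tr$ref == refs_small$te_name & tr$start <= 400 &
    tr$start + 49 >= 400
  al <- pool$truth$alleles
  allele_of_copy <- setNames(al$allele[al$site == 400], al$copy[al$site == 400])
  tally <- table(allele_of_copy[as.character(tr$copy[cover])])
  expect_identical(at$A, as.integer(tally[["A"]]))
  expect_identical(at$G, as.integer(tally[["G"]]))
  expect_identical(at$cov, as.integer(sum(tally)))
})

test_that("copy number is TE coverage over SCG coverage", {
  counts <- uniform_site_counts(refs_small, te_cov = 30L, scg_cov = 5L)
  est <- estimate_copy_number(counts, refs_small, "melanogaster")
  expect_identical(est$copies_per_haploid, 6)
  expect_true(all(est$per_site_copies == 6))

  zero <- uniform_site_counts(refs_small, te_cov = 0L, scg_cov = 5L)
  expect_identical(
    estimate_copy_number(zero, refs_small, "melanogaster")$copies_per_haploid,
    0)

  no_scg <- uniform_site_counts(refs_small, te_cov = 30L, scg_cov = 0L)
  expect_error(estimate_copy_number(no_scg, refs_small, "melanogaster"),
               "undefined")
  expect_error(estimate_copy_number(counts, refs_small, "martian"), "SCG")
})

test_that("synthetic pool recovers its copy number (truth-count oracle)", {
  fixq <- make_test_refs(te_len = 2907, scg_len = 3000, n_diag = 0)
  spec <- pool_spec("melanogaster", n_individuals = 50,
                    copy_number_mean = 10, depth = 50, seed = 1)
  pool <- simulate_pool(spec, fixq$refs)
  aln <- align_reads(pool$reads, fixq$refs, species = "melanogaster")
  est <- estimate_copy_number(pileup(aln, fixq$refs, "melanogaster"),
                              fixq$refs, "melanogaster")
  expect_gt(est$copies_per_haploid, 9)
  expect_lt(est$copies_per_haploid, 11)
  truth_mean <- sum(pool$truth$individuals$te_copies) / (2 * 50)
  expect_lt(abs(est$copies_per_haploid - truth_mean) / truth_mean, 0.05)
})

test_that("normalization and frequencies are invariant to depth scaling", {
  counts <- uniform_site_counts(refs_small, te_cov = 12L, scg_cov = 4L)
  doubled <- counts
  for (b in c("A", "C", "G", "T", "cov")) doubled[[b]] <- 2L * doubled[[b]]
  e1 <- estimate_copy_number(counts, refs_small, "melanogaster")
  e2 <- estimate_copy_number(doubled, refs_small, "melanogaster")
  expect_equal(e1$copies_per_haploid, e2$copies_per_haploid)
  expect_equal(e1$per_site_copies, e2$per_site_copies)
  p1 <- allele_frequencies(counts, refs_small$te_name, min_coverage = 4)
  p2 <- allele_frequencies(doubled, refs_small$te_name, min_coverage = 4)
  expect_equal(p1$freq, p2$freq)
})

test_that("allele_frequencies reports frequencies and missing sites", {
  counts <- uniform_site_counts(refs_small, te_cov = 100L, scg_cov = 10L)
  i <- which(counts$ref == refs_small$te_name & counts$pos == 10)
  counts[i, c("A", "C", "G", "T")] <- c(50L, 0L, 50L, 0L)
  j <- which(counts$ref == refs_small$te_name & counts$pos == 20)
  counts[j, c("A", "C", "G", "T", "cov")] <- c(3L, 0L, 0L, 0L, 3L)

  prof <- allele_frequencies(counts, refs_small$te_name, min_coverage = 10)
  expect_equal(profile_freq(prof, 10, "A"), 0.5)
  expect_equal(profile_freq(prof, 10, "G"), 0.5)
  expect_true(is.na(profile_freq(prof, 20, "A")))  # below threshold
  expect_error(allele_frequencies(counts, "nonesuch"), "unknown")
})

test_that("deletion signature: per-site copies drop by the deleted fraction", {
  fixd <- make_test_refs(te_len = 2907, scg_len = 3000, n_diag = 0)
  spec <- pool_spec("melanogaster", n_individuals = 50,
                    copy_number_mean = 10, deletion_fraction = 0.4,
                    deletion_interval = c(1900, 2200), depth = 50, seed = 2)
  pool <- simulate_pool(spec, fixd$refs)
  aln <- align_reads(pool$reads, fixd$refs, species = "melanogaster")
  est <- estimate_copy_number(pileup(aln, fixd$refs, "melanogaster"),
                              fixd$refs, "melanogaster")
  pos <- as.integer(names(est$per_site_copies))
  inside <- mean(est$per_site_copies[pos >= 2000 & pos <= 2100])
  outside <- mean(est$per_site_copies[(pos >= 500 & pos <= 1500)])
  d_real <- mean(pool$truth$copies$deleted)
  expect_lt(abs(inside / outside - (1 - d_real)), 0.05)
})

test_that("SAM round-trips alignments", {
  spec <- pool_spec("melanogaster", n_individuals = 5, copy_number_mean = 2,
                    depth = 10, read_length = 50, error_rate = 0, seed = 44)
  pool <- simulate_pool(spec, refs_small)
  aln <- align_reads(pool$reads, refs_small, species = "melanogaster")
  path <- tempfile(fileext = ".sam")
  on.exit(unlink(path))
  write_sam(aln, refs_small, path, species = "melanogaster")
  back <- read_sam(path)
  expect_identical(back$ref, aln$ref)
  expect_identical(back$pos, aln$pos)
  expect_identical(back$seq, aln$seq)
  c1 <- pileup(aln, refs_small, species = "melanogaster")
  c2 <- pileup(back, refs_small, species = "melanogaster")
  expect_identical(c1$cov, c2$cov)
})
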