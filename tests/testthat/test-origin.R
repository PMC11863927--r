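pub <- published_freq_rows()

test_that("cross-species SNP table retains divergent sites ranked by difference", {
  mel_prof <- allele_profile(pub$mel)
  sim_prof <- allele_profile(pub$sim)
  tab <- build_snp_table(list(mel_prof), list(sim_prof), threshold = 0.01)
  expect_identical(nrow(tab), 5L)
  expect_identical(tab$site[1], 2040L)
  expect_identical(tab$site[2], 32L)
  expect_true(all(diff(tab$diff) <= 0))
  ## the simulans allele is A at every one of these sites except 652 (C)
  expect_identical(tab$sim_allele[tab$site == 2040], "A")
  expect_identical(tab$sim_allele[tab$site == 652], "C")

  ## identical panels give an empty table
  empty <- build_snp_table(list(mel_prof), list(mel_prof), threshold = 0.01)
  expect_identical(nrow(empty), 0L)
})

test_that("planted divergent sites among uniform ones are recovered exactly", {
  set.seed(31)
  n_sites <- 50
  sites <- sort(sample(1:2900, n_sites))
  planted <- sample(sites, 3)
  base_freq <- function(site) {
    if (site %in% planted) c(A = 0.5, G = 0.5) else c(A = 1)
  }
  mel <- lapply(1:4, function(i) {
    allele_profile(setNames(lapply(sites, base_freq), sites))
  })
  sim <- lapply(1:2, function(i) {
    allele_profile(setNames(lapply(sites, function(s) c(A = 1)), sites))
  })
  tab <- build_snp_table(mel, sim, threshold = 0.01)
  expect_setequal(tab$site, planted)

  ## exhaustive recomputation oracle
  for (s in sites) {
    d <- if (s %in% planted) 0.5 else 0
    row <- tab[tab$site == s, ]
    if (d > 0.01) expect_equal(row$diff, d) else expect_identical(nrow(row), 0L)
  }

  ## uniform simulans panels segregate no SNP among themselves
  within_sim <- build_snp_table(sim[1], sim[2], threshold = 0.01)
  expect_identical(nrow(within_sim), 0L)
})

tab5 <- build_snp_table(list(allele_profile(pub$mel)),
                        list(allele_profile(pub$sim)), threshold = 0.01)

test_that("composite likelihood is the product of simulans-allele frequencies", {
  ## all frequencies 1 -> L = 1
  ones <- allele_profile(list("2040" = c(A = 1), "32" = c(A = 1),
                              "33" = c(A = 1), "517" = c(A = 1),
                              "652" = c(C = 1)))
  expect_equal(composite_likelihood(ones, tab5)$L, 1)

  ## one covered frequency 0 -> L = 0
  zero <- allele_profile(list("2040" = c(G = 1), "32" = c(A = 1),
                              "33" = c(A = 1), "517" = c(A = 1),
                              "652" = c(C = 1)))
  expect_equal(composite_likelihood(zero, tab5)$L, 0)

  ## product oracle: direct sequential multiplication of given frequencies
  f <- c("2040" = 0.008, "32" = 0.414, "33" = 0.021, "517" = 0.021,
         "652" = 0.011)
  prof <- allele_profile(list(
    "2040" = c(A = 0.008, G = 0.992),
    "32"   = c(A = 0.414, T = 0.586),
    "33"   = c(A = 0.021, T = 0.979),
    "517"  = c(A = 0.021, T = 0.979),
    "652"  = c(C = 0.011, A = 0.989)))
  ## build a table whose simulans alleles pick out exactly these f values
  tabf <- build_snp_table(
    list(prof),
    list(allele_profile(list("2040" = c(A = 1), "32" = c(A = 1),
                             "33" = c(A = 1), "517" = c(A = 1),
                             "652" = c(C = 1)))),
    threshold = 0.01)
  L <- composite_likelihood(prof, tabf)
  oracle <- Reduce(`*`, unname(f))
  expect_equal(L$L, oracle, tolerance = 1e-12)
  expect_equal(L$L, 1.6066512e-8, tolerance = 1e-6)
  expect_identical(L$n_snps, 5L)
})

test_that("missing sites follow the missing policy", {
  partial <- allele_profile(list("2040" = c(A = 0.2, G = 0.8),
                                 "32" = c(A = 0.5, T = 0.5)))
  skip_l <- composite_likelihood(partial, tab5, missing_policy = "skip")
  expect_identical(skip_l$n_snps, 2L)
  expect_identical(skip_l$n_missing, 3L)
  expect_equal(skip_l$L, 0.2 * 0.5)

  imp <- composite_likelihood(partial, tab5,
                              missing_policy = "impute-panel-mean")
  expect_identical(imp$n_snps, 5L)
  expect_equal(imp$L, 0.2 * 0.5 * 0.978 * 0.979 * 0.989)

  none <- allele_profile(list("7" = c(A = 1)))
  expect_error(composite_likelihood(none, tab5), "undefined")
})

test_that("L is invariant to SNP order and depth, and monotone in added SNPs", {
  prof <- allele_profile(list("2040" = c(A = 0.3, G = 0.7),
                              "32" = c(A = 0.6, T = 0.4),
                              "33" = c(A = 0.9, T = 0.1),
                              "517" = c(A = 0.9, T = 0.1),
                              "652" = c(C = 0.9, A = 0.1)))
  L1 <- composite_likelihood(prof, tab5)$L
  shuffled <- tab5[c(4, 1, 5, 2, 3), ]
  expect_equal(composite_likelihood(prof, shuffled)$L, L1)

  deep <- prof; deep$cov <- deep$cov * 10L
  expect_equal(composite_likelihood(deep, tab5)$L, L1)

  with_one <- rbind(tab5, tab5[1, ])
  with_one$site[6] <- 99L; with_one$sim_allele[6] <- "A"
  prof99 <- rbind(prof, data.frame(pos = 99L, allele = "A", freq = 1,
                                   cov = 100L))
  class(prof99) <- class(prof)
  expect_equal(composite_likelihood(prof99, with_one)$L, L1)
  prof99$freq[prof99$pos == 99L] <- 0.5
  expect_lt(composite_likelihood(prof99, with_one)$L, L1)
})

test_that("origins rank by likelihood, per sample and per region", {
  mk <- function(id, region, L) {
    structure(list(id = id, region = region, f_sim = L, L = L, n_snps = 5L,
                   n_missing = 0L), class = "origin_likelihood")
  }
  single <- rank_origins(list(mk("s1", "X", 0.1)))
  expect_identical(single$id, "s1")

  two <- rank_origins(list(mk("a", "X", 0.07), mk("b", "Y", 0.19)))
  expect_identical(two$id, c("b", "a"))
  expect_equal(two$L, c(0.19, 0.07))

  byr <- rank_origins(list(mk("a", "X", 0.07), mk("b", "Y", 0.19),
                           mk("c", "Y", 0.18), mk("d", "Z", 0.01)),
                      by_region = TRUE, quantile_threshold = 0.5)
  expect_identical(byr$region[1], "Y")
  expect_identical(byr$n_high[byr$region == "Y"], 2L)
})

test_that("a region with elevated simulans-allele frequencies ranks first", {
  ## planted signal: one region draws its frequencies from a higher Beta
  wins <- 0L
  set.seed(41)
  for (rep_i in 1:100) {
    samples <- list()
    k <- 0L
    for (region in c("high", "low1", "low2")) {
      for (j in 1:5) {
        k <- k + 1L
        a <- if (region == "high") 4 else 1
        f <- stats::rbeta(5, a, 16)
        prof <- allele_profile(list(
          "2040" = c(A = f[1], G = 1 - f[1]),
          "32" = c(A = f[2], T = 1 - f[2]),
          "33" = c(A = f[3], T = 1 - f[3]),
          "517" = c(A = f[4], T = 1 - f[4]),
          "652" = c(C = f[5], A = 1 - f[5])))
        samples[[k]] <- population_sample(paste0(region, j), "melanogaster",
                                          region, prof)
      }
    }
    lks <- lapply(samples, composite_likelihood, table = tab5)
    ranked <- rank_origins(lks, by_region = TRUE)
    if (ranked$region[1] == "high") wins <- wins + 1L
  }
  expect_gte(wins, 95L)
})

test_that("absolute allele copies are deletion-aware", {
  fix <- make_test_refs(te_len = 2907, scg_len = 3000, n_diag = 0)
  prof0 <- allele_profile(list("2040" = c(A = 0, G = 1)))
  cn <- list(te_mean_coverage = 40, scg_mean_coverage = 10,
             copies_per_haploid = 4,
             per_site_copies = c("2040" = 4))
  class(cn) <- "copy_number_estimate"
  s0 <- population_sample("s0", "melanogaster", "X", prof0, copy_number = cn)
  expect_equal(absolute_allele_copies(s0, 2040, "A"), 0)
  prof1 <- allele_profile(list("2040" = c(A = 1)))
  s1 <- population_sample("s1", "melanogaster", "X", prof1, copy_number = cn)
  expect_equal(absolute_allele_copies(s1, 2040, "A"), 4)

  ## synthetic KP-like pool: 10 copies/haploid, 40% deleted over 2040,
  ## remaining copies 50% A -> about 0.6 * 10 * 0.5 = 3 A-copies
  spec <- pool_spec("melanogaster", n_individuals = 50,
                    copy_number_mean = 10,
                    allele_profile = list("2040" = c(A = 0.5, G = 0.5)),
                    deletion_fraction = 0.4,
                    deletion_interval = c(1900, 2200), depth = 50, seed = 3)
  pool <- simulate_pool(spec, fix$refs)
  res <- quantify_pool(pool$reads, fix$refs, "melanogaster")
  samp <- population_sample("kp", "melanogaster", "X", res$profile,
                            copy_number = res$copy_number)
  est <- absolute_allele_copies(samp, 2040, "A")
  expect_lt(abs(est - 3), 0.5)

  ## truth-count oracle: copies per haploid genome that are non-deleted
  ## and carry A at 2040
  tr <- pool$truth
  a_copies <- tr$alleles$copy[tr$alleles$site == 2040 &
                                tr$alleles$allele == "A"]
  live <- tr$copies$copy[!tr$copies$deleted]
  truth_abs <- length(intersect(a_copies, live)) / (2 * 50)
  expect_lt(abs(est - truth_abs), 0.5)

  expect_error(absolute_allele_copies(s1, 100, "A"), "not covered")
})
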