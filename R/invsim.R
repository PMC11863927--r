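#' Parameters of the trap-model invasion simulator
#'
#' The simulator follows a TE invasion in a Wright-Fisher population of `N`
#' diploids under the piRNA-cluster trap model: the genome is a set of
#' `L_sites` discrete insertion slots with free recombination, a fraction
#' `cluster_fraction` of which are piRNA-cluster ("trap") slots.  An
#' individual carrying at least one cluster insertion is
#' transposition-silenced (dominant, individual-level silencing).
#' Non-silenced individuals gain `Poisson(u * n)` new insertions per
#' generation at uniformly chosen slots, and every individual loses
#' `Poisson(x * n)` copies to excision.  Fitness is multiplicative in the
#' total copy number, `(1 - s)^n`; cluster insertions are selectively
#' neutral beyond their silencing effect.
#'
#' @param N Diploid population size (>= 2).
#' @param u Transposition rate per copy per generation, in \[0, 1\].
#' @param x Excision rate per copy per generation, in \[0, 1\].
#' @param cluster_fraction Fraction of insertion slots that are cluster
#'   (trap) slots, in \[0, 1).
#' @param s Selection coefficient per copy, in \[0, 1\].
#' @param n0 Initial TE copies per seeded individual (diploid count).
#' @param seeded_fraction Fraction of founders carrying TEs, in (0, 1\].
#' @param generations Number of generations to simulate.
#' @param replicates Number of replicate populations.
#' @param L_sites Number of insertion slots (default 10000).
#' @param condition Condition label attached to the output series.
#' @param seed Integer seed.
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(N, u, x = 0, cluster_fraction = 0, s = 0,
                       n0 = 2L, seeded_fraction = 1, generations = 60L,
                       replicates = 3L, L_sites = 10000L,
                       condition = "sim", seed = NULL) {
  N <- assert_count(N, "N", lower = 2L)
  assert_scalar_number(u, "u", 0, 1)
  assert_scalar_number(x, "x", 0, 1)
  assert_scalar_number(cluster_fraction, "cluster_fraction", 0, 1 - 1e-12)
  assert_scalar_number(s, "s", 0, 1)
  n0 <- assert_count(n0, "n0", lower = 0L)
  assert_scalar_number(seeded_fraction, "seeded_fraction", 1e-12, 1)
  generations <- assert_count(generations, "generations", lower = 1L)
  replicates <- assert_count(replicates, "replicates", lower = 1L)
  L_sites <- assert_count(L_sites, "L_sites", lower = 1L)
  structure(
    list(N = N, u = u, x = x, cluster_fraction = cluster_fraction, s = s,
         n0 = n0, seeded_fraction = seeded_fraction,
         generations = generations, replicates = replicates,
         L_sites = L_sites, condition = condition, seed = seed),
    class = "sim_params"
  )
}

## One Wright-Fisher generation.  pop: list of integer site vectors
## (diploid insertion multisets).  Returns list(pop, events) where events
## tallies inherited/excised/gained per individual when record_events.
wf_generation <- function(pop, params, n_cluster, record_events = FALSE) {
  N <- params$N
  n <- lengths(pop)
  w <- (1 - params$s)^n
  if (sum(w) <= 0) return(NULL)  # population extinct
  parents <- sample.int(N, 2L * N, replace = TRUE, prob = w)
  newpop <- vector("list", N)
  ev <- if (record_events)
    matrix(0L, N, 3L, dimnames = list(NULL, c("inherited", "excised",
                                              "gained")))
  for (i in seq_len(N)) {
    pa <- pop[[parents[2L * i - 1L]]]
    pb <- pop[[parents[2L * i]]]
    ## free recombination: each parental insertion transmitted w.p. 1/2
    ins <- c(pa[runif(length(pa)) < 0.5], pb[runif(length(pb)) < 0.5])
    n_inh <- length(ins)
    n_exc <- 0L
    if (params$x > 0 && n_inh > 0L) {
      n_exc <- min(rpois(1L, params$x * n_inh), n_inh)
      if (n_exc > 0L) ins <- ins[-sample.int(n_inh, n_exc)]
    }
    n_gain <- 0L
    silenced <- n_cluster > 0L && any(ins <= n_cluster)
    if (!silenced && params$u > 0 && length(ins) > 0L) {
      n_gain <- rpois(1L, params$u * length(ins))
      if (n_gain > 0L) {
        ins <- c(ins, sample.int(params$L_sites, n_gain, replace = TRUE))
      }
    }
    newpop[[i]] <- ins
    if (record_events) ev[i, ] <- c(n_inh, n_exc, n_gain)
  }
  list(pop = newpop, events = if (record_events) ev else NULL)
}

#' Simulate TE invasions under the trap model
#'
#' Runs `params$replicates` independent Wright-Fisher populations for
#' `params$generations` generations and reports, per replicate, the mean
#' TE copies per haploid genome at every generation (generation 0 is the
#' founder state).  Fully reproducible from `params$seed`.  Loss of all
#' TEs or extinction of the population is reported through attributes on
#' each series (`lost`, `extinct`), not raised as an error.
#'
#' @param params A [sim_params()].
#' @param record_events Keep a per-generation event ledger
#'   (inherited/excised/gained per individual) on each series, for
#'   conservation checks on tiny runs.
#' @return List of [invasion_series()], one per replicate, with attributes
#'   `lost` (all TEs lost by the final generation), `extinct`, and
#'   optionally `events`.
#' @export
run_invasion <- function(params, record_events = FALSE) {
  stopifnot(inherits(params, "sim_params"))
  n_cluster <- as.integer(round(params$cluster_fraction * params$L_sites))
  with_seed(params$seed, {
    lapply(seq_len(params$replicates), function(rep_i) {
      N <- params$N
      n_seeded <- max(1L, round(params$seeded_fraction * N))
      pop <- vector("list", N)
      for (i in seq_len(N)) {
        pop[[i]] <- if (i <= n_seeded && params$n0 > 0L) {
          ## founder insertions at uniformly chosen non-cluster slots
          ## (seeding inside a cluster would silence the founder outright)
          lo <- n_cluster + 1L
          sample(seq.int(lo, params$L_sites), params$n0, replace = TRUE)
        } else {
          integer(0)
        }
      }
      mean_copies <- numeric(params$generations + 1L)
      mean_copies[1L] <- sum(lengths(pop)) / (2 * N)
      extinct <- FALSE
      events <- if (record_events) vector("list", params$generations)
      for (g in seq_len(params$generations)) {
        step <- wf_generation(pop, params, n_cluster, record_events)
        if (is.null(step)) {
          extinct <- TRUE
          mean_copies <- mean_copies[seq_len(g)]
          break
        }
        pop <- step$pop
        if (record_events) events[[g]] <- step$events
        mean_copies[g + 1L] <- sum(lengths(pop)) / (2 * N)
      }
      s <- invasion_series(params$condition, rep_i,
                           seq_along(mean_copies) - 1L, mean_copies)
      attr(s, "lost") <- !extinct && mean_copies[length(mean_copies)] == 0
      attr(s, "extinct") <- extinct
      if (record_events) attr(s, "events") <- events
      s
    })
  })
}

#' Plateau level of a simulated trajectory
#'
#' Convenience wrapper delegating to [plateau_estimate()].
#'
#' @param series An [invasion_series()].
#' @param ... Passed to [plateau_estimate()].
#' @return The plateau level (`NA` when no plateau is reached).
#' @export
plateau_of <- function(series, ...) {
  plateau_estimate(series, ...)$plateau_level
}
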