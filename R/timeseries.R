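#' Invasion series: copy-number trajectory of one replicate
#'
#' @param condition Condition label (species, TE variant, regime).
#' @param replicate Replicate identifier.
#' @param generation Integer vector of sampled generations, strictly
#'   increasing.
#' @param copies Copies per haploid genome at each sampled generation
#'   (>= 0).
#' @return An object of class `invasion_series`.
#' @export
invasion_series <- function(condition, replicate, generation, copies) {
  stopifnot(length(generation) == length(copies), length(generation) >= 1L)
  if (is.unsorted(generation, strictly = TRUE)) {
    stop("generations must be strictly increasing within a replicate",
         call. = FALSE)
  }
  if (any(copies < 0)) stop("copy numbers must be >= 0", call. = FALSE)
  structure(
    list(condition = condition, replicate = replicate,
         generation = as.integer(generation), copies = as.numeric(copies)),
    class = "invasion_series"
  )
}

#' Mean copy number at each replicate's latest sampled generation
#'
#' The standard end-point summary of an invasion experiment: the unweighted
#' mean, over replicates, of the copy number at each replicate's final
#' sampled generation.  Replicates sampled at unequal final generations
#' contribute their own final value.
#'
#' @param series_group List of `invasion_series`.
#' @return A single numeric mean.
#' @export
latest_generation_mean <- function(series_group) {
  if (length(series_group) == 0L) stop("empty series group", call. = FALSE)
  finals <- vapply(series_group, function(s) {
    stopifnot(inherits(s, "invasion_series"))
    s$copies[length(s$copies)]
  }, numeric(1))
  mean(finals)
}

#' Detect the plateau of an invasion trajectory
#'
#' The plateau is the level where copy numbers stabilize once the host
#' defense halts the invasion.  `plateau_generation` is the earliest
#' sampled generation from which the least-squares slope over the trailing
#' `window` time points is at most `slope_tol` copies/generation;
#' `plateau_level` is the mean copy number from that generation onward.
#'
#' @param series An `invasion_series`.
#' @param window Number of trailing time points used for the slope fit
#'   (default 3).
#' @param slope_tol Maximum absolute slope, copies per generation
#'   (default 0.1).
#' @return List with `plateau_generation`, `plateau_level` and `plateau`
#'   (logical flag; `FALSE` with `NA` values when the criterion is never
#'   met).
#' @export
plateau_estimate <- function(series, window = 3L, slope_tol = 0.1) {
  stopifnot(inherits(series, "invasion_series"))
  window <- assert_count(window, "window", lower = 2L)
  n <- length(series$generation)
  if (n < window + 1L) {
    stop("series must have at least window + 1 time points", call. = FALSE)
  }
  ## candidate start points: generation index i such that the window of
  ## points ending at i+window-1 exists; the slope is fit over points
  ## i..(i+window-1) and the plateau must hold from i to the end
  for (i in seq_len(n - window + 1L)) {
    idx <- i:(i + window - 1L)
    slope <- unname(coef(lm(series$copies[idx] ~ series$generation[idx]))[2L])
    if (is.na(slope)) slope <- 0
    if (abs(slope) <= slope_tol) {
      return(list(plateau_generation = series$generation[i],
                  plateau_level = mean(series$copies[i:n]),
                  plateau = TRUE))
    }
  }
  list(plateau_generation = NA_integer_, plateau_level = NA_real_,
       plateau = FALSE)
}

#' Compare latest-generation copy numbers between two groups
#'
#' Two-sided two-sample t-test on the latest-generation copy numbers of
#' two groups of replicates.  The default is the unequal-variance (Welch)
#' form; `test_variant = "pooled"` gives the classical equal-variance
#' test.  Degenerate zero-variance groups with different means are
#' reported with an infinite statistic and the limiting p-value 0
#' (statistic 0 and p = 1 when the means coincide).
#'
#' @param group_a,group_b Lists of `invasion_series` (or plain numeric
#'   vectors of end-point copy numbers).
#' @param test_variant `"welch"` (default) or `"pooled"`.
#' @return List with `statistic`, `p_value`, `df`, `mean_a`, `mean_b`.
#' @export
compare_groups <- function(group_a, group_b,
                           test_variant = c("welch", "pooled")) {
  test_variant <- match.arg(test_variant)
  endpoints <- function(g) {
    if (is.numeric(g)) return(as.numeric(g))
    vapply(g, function(s) s$copies[length(s$copies)], numeric(1))
  }
  xa <- endpoints(group_a)
  xb <- endpoints(group_b)
  if (length(xa) < 2L || length(xb) < 2L) {
    stop("need >= 2 replicates per group", call. = FALSE)
  }
  if (sd(xa) == 0 && sd(xb) == 0) {
    if (mean(xa) == mean(xb)) {
      return(list(statistic = 0, p_value = 1, df = NA_real_,
                  mean_a = mean(xa), mean_b = mean(xb)))
    }
    return(list(statistic = sign(mean(xa) - mean(xb)) * Inf, p_value = 0,
                df = NA_real_, mean_a = mean(xa), mean_b = mean(xb)))
  }
  tt <- t.test(xa, xb, var.equal = (test_variant == "pooled"))
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter), mean_a = mean(xa), mean_b = mean(xb))
}

#' Long-format TSV interchange for invasion series
#'
#' Columns `condition`, `replicate`, `generation`, `copies`; one row per
#' sampled time point.
#'
#' @param series_list List of `invasion_series`.
#' @param path TSV path.
#' @return `path` (write) or a list of `invasion_series` (read).
#' @export
write_invasion_series <- function(series_list, path) {
  rows <- lapply(series_list, function(s) {
    data.frame(condition = s$condition, replicate = s$replicate,
               generation = s$generation, copies = s$copies)
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_invasion_series
#' @export
read_invasion_series <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("condition", "replicate", "generation", "copies")
                %in% names(df)))
  key <- paste(df$condition, df$replicate, sep = "\r")
  lapply(split(df, key), function(sub) {
    sub <- sub[order(sub$generation), , drop = FALSE]
    invasion_series(sub$condition[1L], sub$replicate[1L],
                    sub$generation, sub$copies)
  })
}

#' Generations elapsed over a span of years
#'
#' Converts an invasion lag measured in years into generations, assuming a
#' fixed number of generations per year (Drosophila: about 15/year, so a
#' 30-50 year lag spans 450-750 generations).
#'
#' @param years Number of years.
#' @param generations_per_year Generations per year (default 15).
#' @return Number of generations.
#' @export
lag_generations <- function(years, generations_per_year = 15) {
  assert_scalar_number(years, "years", lower = 0)
  assert_scalar_number(generations_per_year, "generations_per_year",
                       lower = 1e-12)
  years * generations_per_year
}
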