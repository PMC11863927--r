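#' @keywords internal
"_PACKAGE"

#' @importFrom stats rbinom rpois runif rnbinom setNames coef lm pt qt quantile sd t.test
#' @importFrom utils read.delim write.table
NULL

DNA_BASES <- c("A", "C", "G", "T")

## Evaluate `expr` with the RNG seeded at `seed`, restoring the caller's RNG
## state afterwards.  All stochastic entry points route through this so that
## results are reproducible from an explicit seed without clobbering the
## global stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  expr
}

## Scalar argument checks ----------------------------------------------------

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("`%s` must be a single number", name), call. = FALSE)
  }
  if (x < lower || x > upper) {
    stop(sprintf("`%s` must be in [%s, %s], got %s", name,
                 format(lower), format(upper), format(x)), call. = FALSE)
  }
  invisible(x)
}

assert_count <- function(x, name, lower = 0L) {
  assert_scalar_number(x, name, lower = lower)
  if (x != as.integer(x)) {
    stop(sprintf("`%s` must be a whole number", name), call. = FALSE)
  }
  invisible(as.integer(x))
}

## Split a vector of equal-length sequence strings into a single base vector.
## Returns list(base = character, offset = 0-based offset within each read).
explode_bases <- function(seqs) {
  if (length(seqs) == 0L) {
    return(list(base = character(0), offset = integer(0), read = integer(0)))
  }
  widths <- nchar(seqs)
  chars <- strsplit(seqs, "", fixed = TRUE)
  list(
    base = unlist(chars, use.names = FALSE),
    offset = unlist(lapply(widths, function(w) seq_len(w) - 1L), use.names = FALSE),
    read = rep(seq_along(seqs), widths)
  )
}
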