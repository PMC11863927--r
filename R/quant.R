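#' Estimate TE copy number by SCG coverage normalization
#'
#' The core quantification step: the haploid copy number of a TE in a
#' pooled sample is its mean coverage divided by the mean coverage of the
#' single-copy genes, since every haploid genome contributes exactly one
#' copy of each SCG.  For example, TE coverage 30 over SCG coverage 5
#' implies roughly 6 TE insertions per haploid genome.  Per-site copy
#' numbers (`per_site_copies`) divide the coverage at each TE position by
#' the SCG normalizer, which makes internal deletions visible as a drop in
#' per-site copies over the deleted interval.
#'
#' @param counts A `site_counts` data.frame covering the TE and the SCGs of
#'   the sample's species.
#' @param refs A [reference_set()].
#' @param species Species label selecting the SCG entries to normalize
#'   against.
#' @param scg_stat Summary of SCG per-position coverage: `"mean"`
#'   (unweighted mean over all SCG positions, pooling the genes; default)
#'   or `"median"`.
#' @param te_zero How zero-coverage TE positions enter the TE mean:
#'   `"include"` (default) or `"exclude"`.
#' @return An object of class `copy_number_estimate`: list with
#'   `te_mean_coverage`, `scg_mean_coverage`, `copies_per_haploid` and
#'   `per_site_copies` (numeric vector indexed by TE position).
#' @export
#' @examples
#' refs <- reference_set("TE", strrep("A", 10),
#'   data.frame(gene = "g", species = "mel", sequence = strrep("C", 10)))
#' counts <- data.frame(ref = rep(c("TE", "g|mel"), each = 10),
#'   pos = rep(1:10, 2), A = rep(c(30L, 0L), each = 10),
#'   C = rep(c(0L, 5L), each = 10), G = 0L, T = 0L,
#'   cov = rep(c(30L, 5L), each = 10))
#' estimate_copy_number(counts, refs, "mel")$copies_per_haploid  # 6
estimate_copy_number <- function(counts, refs, species,
                                 scg_stat = c("mean", "median"),
                                 te_zero = c("include", "exclude")) {
  stopifnot(inherits(refs, "reference_set"))
  scg_stat <- match.arg(scg_stat)
  te_zero <- match.arg(te_zero)
  scgs <- scg_names(refs, species)
  missing_scg <- setdiff(scgs, counts$ref)
  if (length(missing_scg)) {
    stop("no site counts for SCG(s): ", paste(missing_scg, collapse = ", "),
         call. = FALSE)
  }
  scg_cov <- counts$cov[counts$ref %in% scgs]
  scg_mean <- if (scg_stat == "mean") mean(scg_cov) else
    stats::median(scg_cov)
  if (!is.finite(scg_mean) || scg_mean <= 0) {
    stop("SCG coverage is zero; copy number is undefined", call. = FALSE)
  }
  te <- counts[counts$ref == refs$te_name, , drop = FALSE]
  te <- te[order(te$pos), , drop = FALSE]
  te_cov <- te$cov
  te_mean <- if (te_zero == "include") mean(te_cov) else {
    nz <- te_cov[te_cov > 0]
    if (length(nz)) mean(nz) else 0
  }
  if (!is.finite(te_mean)) te_mean <- 0
  structure(
    list(te_mean_coverage = te_mean,
         scg_mean_coverage = scg_mean,
         copies_per_haploid = te_mean / scg_mean,
         per_site_copies = setNames(te_cov / scg_mean, te$pos)),
    class = "copy_number_estimate"
  )
}

#' @export
print.copy_number_estimate <- function(x, ...) {
  cat(sprintf("copy_number_estimate: %.3f copies per haploid genome\n",
              x$copies_per_haploid))
  cat(sprintf("  TE mean coverage %.2f / SCG mean coverage %.2f\n",
              x$te_mean_coverage, x$scg_mean_coverage))
  invisible(x)
}

#' Per-site TE allele frequencies from nucleotide counts
#'
#' Frequencies are nucleotide counts divided by coverage at each position
#' with coverage at least `min_coverage`; positions below the threshold are
#' missing from the profile (not zero), so downstream consumers can tell
#' "no signal" from "absent allele".
#'
#' @param counts A `site_counts` data.frame.
#' @param te_name Reference sequence to profile (typically the TE
#'   consensus).
#' @param min_coverage Minimum coverage for a position to be reported
#'   (default 10).
#' @return An `allele_profile` data.frame with columns `pos`, `allele`,
#'   `freq`, `cov`; one row per (position, allele) with nonzero count.
#' @export
allele_frequencies <- function(counts, te_name, min_coverage = 10L) {
  min_coverage <- assert_count(min_coverage, "min_coverage", lower = 1L)
  sub <- counts[counts$ref == te_name, , drop = FALSE]
  if (nrow(sub) == 0L) {
    stop("unknown reference sequence '", te_name, "'", call. = FALSE)
  }
  sub <- sub[sub$cov >= min_coverage, , drop = FALSE]
  rows <- lapply(DNA_BASES, function(b) {
    nz <- sub[[b]] > 0L
    data.frame(pos = sub$pos[nz], allele = b,
               freq = sub[[b]][nz] / sub$cov[nz], cov = sub$cov[nz])
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$pos, out$allele), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("allele_profile", "data.frame"),
            te_name = te_name, min_coverage = min_coverage)
}

#' Construct an allele profile from known frequencies
#'
#' Builds the same structure as [allele_frequencies()] directly from a
#' site-to-frequency map, e.g. for published frequency tables or for
#' testing.
#'
#' @param freqs Named list: names are 1-based sites, values are named
#'   numeric vectors of allele frequencies.
#' @param cov Nominal coverage recorded for each site (default 100).
#' @param te_name Name recorded for the profiled sequence.
#' @return An `allele_profile` data.frame.
#' @export
allele_profile <- function(freqs, cov = 100L, te_name = "TE") {
  rows <- lapply(names(freqs), function(site) {
    fr <- freqs[[site]]
    data.frame(pos = as.integer(site), allele = names(fr),
               freq = as.numeric(fr), cov = cov)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$pos, out$allele), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("allele_profile", "data.frame"),
            te_name = te_name, min_coverage = NA_integer_)
}

#' Look up an allele frequency in a profile
#'
#' @param profile An `allele_profile`.
#' @param site 1-based position.
#' @param allele Nucleotide.
#' @return The frequency; 0 when the site is covered but the allele absent;
#'   `NA` when the site is missing from the profile (below the coverage
#'   threshold).
#' @export
profile_freq <- function(profile, site, allele) {
  at <- profile[profile$pos == site, , drop = FALSE]
  if (nrow(at) == 0L) return(NA_real_)
  hit <- at$freq[at$allele == allele]
  if (length(hit) == 0L) 0 else hit[[1L]]
}

#' Quantify a pooled sample end to end
#'
#' Convenience wrapper chaining [trim_reads()], [align_reads()],
#' [pileup()], [estimate_copy_number()] and [allele_frequencies()].
#'
#' @param reads Named character vector of reads (or `NULL` when `sam` is
#'   given).
#' @param refs A [reference_set()].
#' @param species Species label of the sample.
#' @param sam Optional path to an externally produced SAM file used instead
#'   of the internal aligner.
#' @param trim_to Read length to trim to before alignment.
#' @param min_coverage Coverage threshold for allele calls.
#' @param ... Passed on to [align_reads()].
#' @return List with `counts`, `copy_number` and `profile`.
#' @export
quantify_pool <- function(reads, refs, species, sam = NULL,
                          trim_to = 100L, min_coverage = 10L, ...) {
  aln <- if (!is.null(sam)) {
    read_sam(sam)
  } else {
    align_reads(trim_reads(reads, target_length = trim_to), refs,
                species = species, ...)
  }
  counts <- pileup(aln, refs, species = species)
  list(
    counts = counts,
    copy_number = estimate_copy_number(counts, refs, species),
    profile = allele_frequencies(counts, refs$te_name,
                                 min_coverage = min_coverage)
  )
}
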