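#' A population sample for origin inference
#'
#' Bundles the quantities the origin analysis needs for one sample: its
#' species and sampling region, the TE allele profile, the copy-number
#' estimate (for deletion-aware absolute allele copies) and the
#' contamination screen value.
#'
#' @param id Sample identifier.
#' @param species `"melanogaster"` or `"simulans"`.
#' @param region Free-text region label.
#' @param profile An `allele_profile` for the TE.
#' @param copy_number Optional `copy_number_estimate`.
#' @param contamination Optional contamination screen value.
#' @return An object of class `population_sample`.
#' @export
population_sample <- function(id, species, region, profile,
                              copy_number = NULL, contamination = NA_real_) {
  species <- match.arg(species, c("melanogaster", "simulans"))
  stopifnot(inherits(profile, "allele_profile"))
  structure(
    list(id = id, species = species, region = region, profile = profile,
         copy_number = copy_number,
         contamination = as.numeric(contamination)),
    class = "population_sample"
  )
}

## mean per-allele frequency at each site over the samples covering it
panel_means <- function(samples) {
  prof <- lapply(samples, function(s) {
    df <- as.data.frame(s$profile)[, c("pos", "allele", "freq")]
    df$sample <- s$id
    df
  })
  df <- do.call(rbind, prof)
  ## samples covering a site but lacking an allele contribute frequency 0
  ## for that allele, so means are over samples covering the site
  covered <- unique(df[, c("pos", "sample")])
  n_cover <- table(covered$pos)
  agg <- stats::aggregate(freq ~ pos + allele, data = df, FUN = sum)
  agg$freq <- agg$freq / as.numeric(n_cover[as.character(agg$pos)])
  agg$n_samples <- as.numeric(n_cover[as.character(agg$pos)])
  agg
}

#' Build the cross-species segregating-SNP table
#'
#' For each TE site, per-species mean allele frequencies are unweighted
#' means over the samples covering that site (per-sample weighting, so deep
#' samples do not dominate).  A site is retained when its mean absolute
#' frequency difference between the species — summed over alleles and
#' halved — exceeds `threshold`.  Rows are sorted by descending
#' difference.  The "simulans allele" of each retained site is the major
#' allele among the simulans samples.
#'
#' @param mel_samples,sim_samples Lists of `population_sample` (or bare
#'   `allele_profile` objects) for the two species.
#' @param threshold Minimum mean frequency difference (default 0.01).
#' @return A `segregating_snp_table` data.frame with columns `site`,
#'   `alleles` (slash-separated), `freq_mel`, `freq_sim` (slash-separated,
#'   same order), `sim_allele`, `sim_allele_freq_mel`, `diff`.
#' @export
build_snp_table <- function(mel_samples, sim_samples, threshold = 0.01) {
  assert_scalar_number(threshold, "threshold", lower = 0)
  as_samples <- function(x, sp) {
    lapply(seq_along(x), function(i) {
      s <- x[[i]]
      if (inherits(s, "population_sample")) s else
        population_sample(paste0(sp, i), sp, region = "", profile = s)
    })
  }
  mel <- panel_means(as_samples(mel_samples, "melanogaster"))
  sim <- panel_means(as_samples(sim_samples, "simulans"))

  sites <- intersect(unique(mel$pos), unique(sim$pos))
  dropped <- setdiff(union(unique(mel$pos), unique(sim$pos)), sites)

  rows <- lapply(sites, function(p) {
    fm <- setNames(mel$freq[mel$pos == p], mel$allele[mel$pos == p])
    fs <- setNames(sim$freq[sim$pos == p], sim$allele[sim$pos == p])
    alleles <- union(names(fm), names(fs))
    fm <- setNames(ifelse(alleles %in% names(fm), fm[alleles], 0), alleles)
    fs <- setNames(ifelse(alleles %in% names(fs), fs[alleles], 0), alleles)
    d <- sum(abs(fm - fs)) / 2
    sim_allele <- alleles[which.max(fs)]
    data.frame(site = p,
               alleles = paste(alleles, collapse = "/"),
               freq_mel = paste(formatC(fm, format = "fg"), collapse = "/"),
               freq_sim = paste(formatC(fs, format = "fg"), collapse = "/"),
               sim_allele = sim_allele,
               sim_allele_freq_mel = unname(fm[sim_allele]),
               diff = d, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[tab$diff > threshold, , drop = FALSE]
  tab <- tab[order(-tab$diff, tab$site), , drop = FALSE]
  rownames(tab) <- NULL
  structure(tab, class = c("segregating_snp_table", "data.frame"),
            threshold = threshold, dropped_sites = dropped)
}

#' Composite likelihood of the horizontal-transfer origin for one sample
#'
#' Multiplies, over the SNPs of a segregating-SNP table, the sample's
#' frequency of the simulans allele: `L = prod_i f_i_sim`.  The sample
#' with the highest L carries the simulans alleles at the highest joint
#' frequency and is therefore closest to the putative source of the
#' horizontal transfer.  Sites missing from the sample's profile (below
#' the coverage threshold) are handled per `missing_policy`: skipped and
#' flagged (default), or imputed with the melanogaster panel mean from
#' the table.  The covered-SNP count is reported because L values with
#' unequal support are only comparable with care.
#'
#' @param sample A `population_sample` (melanogaster) or bare
#'   `allele_profile`.
#' @param table A `segregating_snp_table`.
#' @param missing_policy `"skip"` (default) or `"impute-panel-mean"`.
#' @return An `origin_likelihood` list: `id`, `region`, `f_sim` (named
#'   per-site vector actually used), `L`, `n_snps` (covered), `n_missing`.
#' @export
composite_likelihood <- function(sample, table,
                                 missing_policy = c("skip",
                                                    "impute-panel-mean")) {
  missing_policy <- match.arg(missing_policy)
  if (nrow(table) == 0L) stop("empty SNP table", call. = FALSE)
  if (inherits(sample, "allele_profile")) {
    sample <- population_sample("sample", "melanogaster", "", sample)
  }
  stopifnot(inherits(sample, "population_sample"))
  f <- vapply(seq_len(nrow(table)), function(i) {
    profile_freq(sample$profile, table$site[i], table$sim_allele[i])
  }, numeric(1))
  names(f) <- table$site
  miss <- is.na(f)
  if (any(miss) && missing_policy == "impute-panel-mean") {
    f[miss] <- table$sim_allele_freq_mel[miss]
    miss <- rep(FALSE, length(f))
  }
  used <- f[!miss]
  if (length(used) == 0L) {
    stop("no SNP of the table is covered in the sample; ",
         "likelihood undefined", call. = FALSE)
  }
  structure(
    list(id = sample$id, region = sample$region, f_sim = used,
         L = prod(used), n_snps = length(used), n_missing = sum(miss)),
    class = "origin_likelihood"
  )
}

#' Rank candidate origins by composite likelihood
#'
#' Samples are sorted by descending L.  With `by_region = TRUE` each
#' region is summarized by its maximum sample L and by its count of
#' samples exceeding the `quantile_threshold` quantile of all L values —
#' distinguishing regions where several samples score high from regions
#' carried by a single outlier.
#'
#' @param likelihoods List of `origin_likelihood`.
#' @param by_region Summarize per region instead of per sample.
#' @param quantile_threshold Quantile of all L values above which a sample
#'   counts as "high-likelihood" in the regional summary (default 0.9).
#' @return A data.frame ranked by descending likelihood: per sample
#'   (`id`, `region`, `L`, `n_snps`) or per region (`region`, `max_L`,
#'   `n_high`, `n_samples`).
#' @export
rank_origins <- function(likelihoods, by_region = FALSE,
                         quantile_threshold = 0.9) {
  if (length(likelihoods) == 0L) stop("no likelihoods given", call. = FALSE)
  df <- data.frame(
    id = vapply(likelihoods, `[[`, "", "id"),
    region = vapply(likelihoods, `[[`, "", "region"),
    L = vapply(likelihoods, `[[`, numeric(1), "L"),
    n_snps = vapply(likelihoods, function(x) as.integer(x$n_snps),
                    integer(1)),
    stringsAsFactors = FALSE
  )
  if (!by_region) {
    df <- df[order(-df$L), , drop = FALSE]
    rownames(df) <- NULL
    return(df)
  }
  cut <- quantile(df$L, quantile_threshold, names = FALSE)
  out <- do.call(rbind, lapply(split(df, df$region), function(sub) {
    data.frame(region = sub$region[1L], max_L = max(sub$L),
               n_high = sum(sub$L >= cut), n_samples = nrow(sub))
  }))
  out <- out[order(-out$max_L), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Absolute copies of an allele at a TE site
#'
#' Converts an allele frequency at a site into copies per haploid genome
#' carrying that allele: `frequency x per-site copy number`.  Because the
#' per-site copy number uses the coverage at that site, the estimate is
#' immune to internal deletions (e.g. KP-like elements) that remove the
#' site from part of the TE copies: deleted copies contribute neither to
#' the frequency nor to the site's coverage.
#'
#' @param sample A `population_sample` with a `copy_number` estimate.
#' @param site 1-based TE consensus site.
#' @param allele Nucleotide.
#' @return Copies per haploid genome carrying `allele` at `site`.
#' @export
absolute_allele_copies <- function(sample, site, allele) {
  stopifnot(inherits(sample, "population_sample"))
  if (is.null(sample$copy_number)) {
    stop("sample has no copy-number estimate", call. = FALSE)
  }
  f <- profile_freq(sample$profile, site, allele)
  if (is.na(f)) {
    stop("site ", site, " is not covered in the sample profile",
         call. = FALSE)
  }
  psc <- sample$copy_number$per_site_copies[as.character(site)]
  if (is.na(psc)) {
    stop("site ", site, " has no per-site copy number", call. = FALSE)
  }
  unname(f * psc)
}

#' Write a segregating-SNP table or origin ranking as TSV
#'
#' @param x A `segregating_snp_table` or the data.frame from
#'   [rank_origins()].
#' @param path TSV path.
#' @return `path`, invisibly.
#' @export
write_origin_table <- function(x, path) {
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
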