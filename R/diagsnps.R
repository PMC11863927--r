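#' Find species-diagnostic SNPs in single-copy genes
#'
#' A site in an SCG is diagnostic for a species pair when every reference
#' strain of species a is fixed (frequency >= `fixity_threshold`) for one
#' allele and every strain of species b is fixed for a different allele.
#' Such sites allow cross-species read contamination to be detected in a
#' sample: any appreciable frequency of the other species' allele at
#' diagnostic sites implies foreign reads.
#'
#' Sites uncovered (below `min_coverage`) in any strain are excluded and
#' counted in the `n_uncovered` attribute.  Sites where either species
#' shows a third allele above `1 - fixity_threshold` are excluded, since
#' tri-allelic sites weaken the inference.
#'
#' @param counts_a,counts_b Lists of `site_counts`, one per reference
#'   strain of species a / b (the study design uses 3 strains per
#'   species).
#' @param genes Character vector of SCG reference names to scan shared by
#'   both species' counts (e.g. the gene part of `gene|species` headers is
#'   matched when the full names differ between species).
#' @param fixity_threshold Minimum within-strain major-allele frequency to
#'   call a strain fixed; default 0.99 tolerates sequencing error in the
#'   reference strains.
#' @param min_coverage Minimum per-strain coverage for a site to be
#'   assessed.
#' @return A `diagnostic_snp_set` data.frame with columns `gene`, `pos`,
#'   `allele_a`, `allele_b`.
#' @export
find_diagnostic_snps <- function(counts_a, counts_b, genes = NULL,
                                 fixity_threshold = 0.99,
                                 min_coverage = 10L) {
  assert_scalar_number(fixity_threshold, "fixity_threshold", 0.5 + 1e-12, 1)
  stopifnot(length(counts_a) >= 1L, length(counts_b) >= 1L)

  ## gene key: strip the trailing |species so orthologs line up
  gene_key <- function(ref) sub("\\|[^|]*$", "", ref)
  prep <- function(counts) {
    df <- as.data.frame(counts)
    df$gene <- gene_key(df$ref)
    df
  }
  a <- lapply(counts_a, prep)
  b <- lapply(counts_b, prep)
  if (is.null(genes)) {
    genes <- intersect(unique(a[[1L]]$gene), unique(b[[1L]]$gene))
  }

  ## per strain, per (gene, pos): major allele + its frequency + third-allele
  ## presence; returns NA allele when uncovered
  strain_calls <- function(df, gene) {
    sub <- df[df$gene == gene, , drop = FALSE]
    sub <- sub[order(sub$pos), , drop = FALSE]
    m <- as.matrix(sub[, DNA_BASES])
    covered <- sub$cov >= min_coverage
    major_i <- max.col(m, ties.method = "first")
    major_f <- m[cbind(seq_len(nrow(m)), major_i)] / pmax(sub$cov, 1L)
    ## frequency of alleles other than the top two
    sorted2 <- apply(m, 1L, function(r) sum(r) - sum(sort(r, decreasing = TRUE)[1:2]))
    third_f <- sorted2 / pmax(sub$cov, 1L)
    data.frame(pos = sub$pos,
               allele = ifelse(covered, DNA_BASES[major_i], NA),
               freq = ifelse(covered, major_f, NA),
               third = ifelse(covered, third_f, NA))
  }

  out <- list()
  n_uncovered <- 0L
  for (g in genes) {
    ca <- lapply(a, strain_calls, gene = g)
    cb <- lapply(b, strain_calls, gene = g)
    pos <- ca[[1L]]$pos
    get_col <- function(calls, col) {
      sapply(calls, function(x) x[[col]][match(pos, x$pos)])
    }
    al_a <- get_col(ca, "allele"); fr_a <- get_col(ca, "freq")
    al_b <- get_col(cb, "allele"); fr_b <- get_col(cb, "freq")
    th_a <- get_col(ca, "third"); th_b <- get_col(cb, "third")
    if (is.null(dim(al_a))) al_a <- matrix(al_a, ncol = 1L)
    if (is.null(dim(al_b))) al_b <- matrix(al_b, ncol = 1L)
    if (is.null(dim(fr_a))) fr_a <- matrix(fr_a, ncol = 1L)
    if (is.null(dim(fr_b))) fr_b <- matrix(fr_b, ncol = 1L)
    if (is.null(dim(th_a))) th_a <- matrix(th_a, ncol = 1L)
    if (is.null(dim(th_b))) th_b <- matrix(th_b, ncol = 1L)

    uncovered <- apply(is.na(al_a), 1L, any) | apply(is.na(al_b), 1L, any)
    n_uncovered <- n_uncovered + sum(uncovered)

    same_a <- apply(al_a, 1L, function(x) length(unique(x)) == 1L)
    same_b <- apply(al_b, 1L, function(x) length(unique(x)) == 1L)
    fixed_a <- apply(fr_a >= fixity_threshold, 1L, all)
    fixed_b <- apply(fr_b >= fixity_threshold, 1L, all)
    tri <- apply(th_a > (1 - fixity_threshold), 1L, any) |
      apply(th_b > (1 - fixity_threshold), 1L, any)
    diff_ab <- al_a[, 1L] != al_b[, 1L]

    ok <- !uncovered & same_a & same_b & fixed_a & fixed_b & diff_ab &
      !ifelse(is.na(tri), TRUE, tri)
    ok[is.na(ok)] <- FALSE
    if (any(ok)) {
      out[[g]] <- data.frame(gene = g, pos = pos[ok],
                             allele_a = al_a[ok, 1L],
                             allele_b = al_b[ok, 1L],
                             stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(gene = character(0), pos = integer(0),
               allele_a = character(0), allele_b = character(0))
  rownames(res) <- NULL
  structure(res, class = c("diagnostic_snp_set", "data.frame"),
            fixity_threshold = fixity_threshold, n_uncovered = n_uncovered)
}

#' Screen a sample for cross-species contamination
#'
#' Returns the mean, over covered diagnostic sites, of the frequency of the
#' other species' allele — an estimate of the contaminating read fraction
#' in \[0, 1\].  A pure sample of the expected species scores ~0 (plus the
#' sequencing error rate); a sample made entirely of the other species'
#' reads scores ~1.
#'
#' @param sample_counts A `site_counts` for the sample (SCG references
#'   named `gene|species` or matching `snps$gene` directly).
#' @param snps A `diagnostic_snp_set` from [find_diagnostic_snps()].
#' @param expected_species `"a"` or `"b"`: which side of the SNP set the
#'   sample is supposed to be.
#' @param min_coverage Minimum coverage for a diagnostic site to enter the
#'   mean.
#' @return A single numeric: the estimated contamination fraction, with
#'   attribute `n_sites` (covered diagnostic sites used).
#' @export
contamination_screen <- function(sample_counts, snps,
                                 expected_species = c("a", "b"),
                                 min_coverage = 10L) {
  expected_species <- match.arg(expected_species)
  if (nrow(snps) == 0L) {
    stop("empty diagnostic SNP set", call. = FALSE)
  }
  df <- as.data.frame(sample_counts)
  df$gene <- sub("\\|[^|]*$", "", df$ref)
  other_allele <- if (expected_species == "a") snps$allele_b else snps$allele_a
  freqs <- rep(NA_real_, nrow(snps))
  for (i in seq_len(nrow(snps))) {
    row <- df[df$gene == snps$gene[i] & df$pos == snps$pos[i], , drop = FALSE]
    if (nrow(row) == 0L || row$cov[1L] < min_coverage) next
    freqs[i] <- row[[other_allele[i]]][1L] / row$cov[1L]
  }
  used <- !is.na(freqs)
  if (!any(used)) {
    stop("no diagnostic site covered in the sample; screen undefined",
         call. = FALSE)
  }
  structure(mean(freqs[used]), n_sites = sum(used))
}

#' Contamination gate
#'
#' A sample passes the gate when its screen estimate does not exceed
#' `cutoff` (default 0.01).
#'
#' @param screen_value Value returned by [contamination_screen()].
#' @param cutoff Maximum tolerated contamination fraction.
#' @return Logical.
#' @export
passes_contamination_gate <- function(screen_value, cutoff = 0.01) {
  as.numeric(screen_value) <= cutoff
}

#' Write / read a diagnostic SNP set as TSV
#'
#' @param snps A `diagnostic_snp_set`.
#' @param path TSV path.
#' @return `path` (write) or a `diagnostic_snp_set` (read).
#' @export
write_diagnostic_snps <- function(snps, path) {
  write.table(as.data.frame(snps), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_diagnostic_snps
#' @export
read_diagnostic_snps <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("gene", "pos", "allele_a", "allele_b") %in% names(df)))
  structure(df, class = c("diagnostic_snp_set", "data.frame"))
}
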