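## Shared synthetic fixtures.  All references are generated from a fixed
## seed; SCGs are long relative to the read length so edge-coverage falloff
## is negligible in coverage means.

rand_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## A two-species reference set: TE consensus + 3 SCG ortholog pairs.
## Orthologs are identical apart from `n_diag` planted fixed differences
## per gene (the ground truth for diagnostic SNP recovery).  Returns
## list(refs, diag) where diag is a data.frame(gene, pos, allele_mel,
## allele_sim).
make_test_refs <- function(te_len = 2907, scg_len = 3000, n_diag = 7,
                           seed = 99) {
  withr_seed <- function(expr) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    expr
  }
  withr_seed({
    te <- rand_seq(te_len)
    genes <- c("rhi", "tj", "RpL32")
    scg_rows <- list()
    diag <- list()
    for (g in genes) {
      mel <- rand_seq(scg_len)
      sim <- mel
      pos <- integer(0)
      al_m <- al_s <- character(0)
      if (n_diag > 0) {
        ## keep planted SNPs well separated so no read spans two of them
        pos <- sort(sample(seq(150, scg_len - 150, by = 120), n_diag))
        for (p in pos) {
          m_allele <- substr(mel, p, p)
          s_allele <- sample(setdiff(c("A", "C", "G", "T"), m_allele), 1)
          substr(sim, p, p) <- s_allele
          al_m <- c(al_m, m_allele)
          al_s <- c(al_s, s_allele)
        }
      }
      scg_rows[[paste0(g, "_mel")]] <-
        data.frame(gene = g, species = "melanogaster", sequence = mel)
      scg_rows[[paste0(g, "_sim")]] <-
        data.frame(gene = g, species = "simulans", sequence = sim)
      if (length(pos)) {
        diag[[g]] <- data.frame(gene = g, pos = pos,
                                allele_mel = al_m, allele_sim = al_s)
      }
    }
    list(
      refs = reference_set("PPI251", te, do.call(rbind, scg_rows)),
      diag = if (length(diag)) do.call(rbind, diag) else NULL
    )
  })
}

## Ideal alignments straight from the truth record (perfect mapper):
## every read is placed at its true position.  Contaminant reads are
## mapped onto the orthologous reference of `frame_species`, which shares
## coordinates with their own species' SCG by construction.
truth_alignments <- function(pool, frame_species = "melanogaster") {
  tr <- pool$truth$reads
  ref <- sub("\\|[^|]*$", paste0("|", frame_species),
             tr$ref)
  ref[!grepl("|", tr$ref, fixed = TRUE)] <-
    tr$ref[!grepl("|", tr$ref, fixed = TRUE)]
  structure(
    data.frame(id = tr$id, ref = ref, pos = tr$start,
               seq = unname(pool$reads[tr$id]),
               mismatches = 0L, stringsAsFactors = FALSE),
    class = c("alignments", "data.frame")
  )
}

## Brute-force per-base coverage over emitted read coordinates for one
## reference: independent of pileup().
brute_force_coverage <- function(truth_reads, ref, ref_len, read_length) {
  cov <- integer(ref_len)
  sub <- truth_reads[truth_reads$ref == ref, , drop = FALSE]
  for (i in seq_len(nrow(sub))) {
    idx <- sub$start[i]:(sub$start[i] + read_length - 1L)
    cov[idx] <- cov[idx] + 1L
  }
  cov
}

## Uniform site counts: every position of every reference gets the same
## coverage, attributed to the reference's own base.
uniform_site_counts <- function(refs, te_cov, scg_cov,
                                species = "melanogaster") {
  target <- ref_sequences(refs, species)
  rows <- lapply(names(target), function(nm) {
    L <- nchar(target[[nm]])
    covv <- if (nm == refs$te_name) te_cov else scg_cov
    base <- strsplit(target[[nm]], "")[[1L]]
    df <- data.frame(ref = nm, pos = seq_len(L), A = 0L, C = 0L, G = 0L,
                     T = 0L, cov = covv)
    for (b in c("A", "C", "G", "T")) df[[b]][base == b] <- covv
    df
  })
  structure(do.call(rbind, rows), class = c("site_counts", "data.frame"))
}

## Table of cross-species TE SNP frequencies used in the origin tests:
## five segregating sites, per-species mean allele frequencies.
published_freq_rows <- function() {
  list(
    mel = list(
      "2040" = c(G = 0.992, A = 0.008),
      "32"   = c(T = 0.535, A = 0.414, G = 0.051),
      "33"   = c(A = 0.978, T = 0.021),
      "517"  = c(A = 0.979, T = 0.021),
      "652"  = c(C = 0.989, A = 0.011)
    ),
    sim = list(
      "2040" = c(G = 0, A = 1),
      "32"   = c(T = 0, A = 1, G = 0),
      "33"   = c(A = 1, T = 0),
      "517"  = c(A = 1, T = 0),
      "652"  = c(C = 1, A = 0)
    )
  )
}
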