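#' Specification of a synthetic pooled sample
#'
#' Describes a pooled sequencing sample of `n_individuals` diploid flies,
#' each carrying TE insertions, from which single-end reads are drawn.  The
#' generator emulates Pool-Seq of experimental or natural populations with
#' known ground truth: every read is attributable to an individual, a source
#' sequence and (for TE reads) a specific insertion copy.
#'
#' TE copy counts per individual are Poisson with mean
#' `2 * copy_number_mean` (diploid; dispersed-insertion assumption), or
#' fixed at exactly that number when `copy_number_dist = "fixed"`.  Each
#' copy carries, at every profiled consensus site, an allele drawn from
#' `allele_profile`, and is internally deleted with probability
#' `deletion_fraction`, in which case it emits no reads from within
#' `deletion_interval` (a KP-element-like internal deletion).
#'
#' @param species Species label of the pool; must have SCG entries in the
#'   reference set.
#' @param n_individuals Number of diploid individuals in the pool.
#' @param copy_number_mean Mean TE copies per haploid genome (>= 0).
#' @param allele_profile Named list: names are 1-based TE consensus sites,
#'   values are named numeric vectors of allele fractions summing to 1
#'   (fraction of TE copies carrying each allele).
#' @param deletion_fraction Fraction of TE copies carrying the internal
#'   deletion, in \[0, 1\].
#' @param deletion_interval Closed 1-based site range removed by the
#'   deletion (length-2 integer vector).
#' @param contamination_fraction Fraction of output reads drawn from an
#'   SCG-only pool of `contaminant_species`, in \[0, 1\].
#' @param contaminant_species Species supplying contaminating reads;
#'   required when `contamination_fraction > 0`.
#' @param depth Target SCG coverage (fold coverage per haploid genome
#'   equivalent; TE coverage is then `depth * copy_number_mean`).
#' @param read_length Read length in bp.
#' @param error_rate Per-base substitution error rate, in \[0, 1).
#' @param copy_number_dist `"poisson"` (default) or `"fixed"`.
#' @param seed Integer seed; the sample is fully reproducible from it.
#'
#' @return An object of class `pool_spec`.
#' @export
pool_spec <- function(species,
                      n_individuals,
                      copy_number_mean,
                      allele_profile = list(),
                      deletion_fraction = 0,
                      deletion_interval = c(1L, 1L),
                      contamination_fraction = 0,
                      contaminant_species = NULL,
                      depth = 50,
                      read_length = 100L,
                      error_rate = 0.001,
                      copy_number_dist = c("poisson", "fixed"),
                      seed = NULL) {
  copy_number_dist <- match.arg(copy_number_dist)
  n_individuals <- assert_count(n_individuals, "n_individuals", lower = 1L)
  assert_scalar_number(copy_number_mean, "copy_number_mean", lower = 0)
  assert_scalar_number(deletion_fraction, "deletion_fraction", 0, 1)
  assert_scalar_number(contamination_fraction, "contamination_fraction", 0, 1)
  assert_scalar_number(depth, "depth", lower = 1e-12)
  read_length <- assert_count(read_length, "read_length", lower = 1L)
  assert_scalar_number(error_rate, "error_rate", 0, 1 - 1e-12)
  stopifnot(length(deletion_interval) == 2L,
            deletion_interval[1] <= deletion_interval[2])
  if (contamination_fraction > 0 && is.null(contaminant_species)) {
    stop("`contaminant_species` is required when contamination_fraction > 0",
         call. = FALSE)
  }
  for (site in names(allele_profile)) {
    fr <- allele_profile[[site]]
    if (abs(sum(fr) - 1) > 1e-9) {
      stop("allele fractions at site ", site, " must sum to 1", call. = FALSE)
    }
    if (is.null(names(fr)) || !all(names(fr) %in% DNA_BASES)) {
      stop("allele_profile entries must be named by A/C/G/T", call. = FALSE)
    }
  }
  structure(
    list(species = species, n_individuals = n_individuals,
         copy_number_mean = copy_number_mean, allele_profile = allele_profile,
         deletion_fraction = deletion_fraction,
         deletion_interval = as.integer(deletion_interval),
         contamination_fraction = contamination_fraction,
         contaminant_species = contaminant_species,
         depth = depth, read_length = read_length, error_rate = error_rate,
         copy_number_dist = copy_number_dist, seed = seed),
    class = "pool_spec"
  )
}

## Draw reads uniformly from one source sequence at per-copy coverage `cov`.
## Returns a data.frame of (start, seq) in source coordinates; positions are
## uniform over valid start sites so that every interior base has expected
## coverage `cov` exactly (reads never run past the sequence end).
draw_reads_from <- function(seq, cov, read_length) {
  L <- nchar(seq)
  n_start <- L - read_length + 1L
  if (n_start < 1L) {
    return(data.frame(start = integer(0), seq = character(0)))
  }
  n_reads <- rpois(1L, cov * n_start / read_length)
  if (n_reads == 0L) {
    return(data.frame(start = integer(0), seq = character(0)))
  }
  start <- sample.int(n_start, n_reads, replace = TRUE)
  data.frame(start = start,
             seq = substring(seq, start, start + read_length - 1L))
}

## Apply substitution errors at per-base rate `e` to a character vector of
## equal-length reads.  Each erroneous base is replaced by a uniformly
## chosen different base.
apply_errors <- function(seqs, e) {
  if (e <= 0 || length(seqs) == 0L) return(seqs)
  rl <- nchar(seqs[1L])
  n_err <- rbinom(length(seqs), rl, e)
  hit <- which(n_err > 0L)
  for (i in hit) {
    pos <- sample.int(rl, n_err[i])
    chars <- strsplit(seqs[i], "", fixed = TRUE)[[1L]]
    for (p in pos) {
      chars[p] <- sample(setdiff(DNA_BASES, chars[p]), 1L)
    }
    seqs[i] <- paste(chars, collapse = "")
  }
  seqs
}

#' Simulate a pooled sequencing sample with known ground truth
#'
#' Emits single-end reads from (i) two haploid SCG genome copies per
#' individual and (ii) each individual's TE copies.  Expected SCG coverage
#' equals `spec$depth`; expected TE coverage equals
#' `depth * copy_number_mean` (per-copy coverage matches a haploid SCG
#' copy, so coverage normalization recovers the copy number).  Internally
#' deleted copies emit no reads from within the deletion interval and no
#' junction-spanning reads, mimicking what a gapless aligner retains from a
#' KP-like derivative.  Substitution errors are applied per base at
#' `error_rate`.  Reads are uniformly positioned with wraparound disallowed.
#'
#' Read names encode the truth (`read|ind=..|ref=..|copy=..|pos=..|sp=..`)
#' so oracle checks need no auxiliary lookups; the same information is
#' tabulated in the returned truth record.
#'
#' @param spec A [pool_spec()].
#' @param refs A [reference_set()] containing the TE consensus and the SCGs
#'   of `spec$species` (and of `spec$contaminant_species` when
#'   contamination is requested).
#' @return A list with elements:
#'   \describe{
#'     \item{reads}{named character vector of read sequences.}
#'     \item{truth}{a `truth_record`: `individuals` (per-individual TE copy
#'       counts), `copies` (per-copy deletion flag), `alleles` (per-copy
#'       allele assignment at each profiled site), `reads` (per-read origin
#'       including contaminant flag), `contamination_reads` (realized
#'       contaminating read count).}
#'   }
#' @export
simulate_pool <- function(spec, refs) {
  stopifnot(inherits(spec, "pool_spec"), inherits(refs, "reference_set"))
  te_len <- nchar(refs$te_sequence)
  sites <- as.integer(names(spec$allele_profile))
  if (length(sites) && (any(sites < 1L) || any(sites > te_len))) {
    stop("allele_profile sites outside the TE consensus", call. = FALSE)
  }
  if (any(spec$deletion_interval > te_len) || any(spec$deletion_interval < 1L)) {
    stop("deletion_interval outside the TE consensus", call. = FALSE)
  }
  species_all <- spec$species
  if (spec$contamination_fraction > 0) {
    species_all <- c(species_all, spec$contaminant_species)
  }
  min_ref <- min(nchar(ref_sequences(refs, species_all)))
  if (spec$read_length > min_ref) {
    stop("read_length longer than the shortest reference sequence",
         call. = FALSE)
  }

  with_seed(spec$seed, {
    main <- simulate_species_reads(spec, refs, include_te = TRUE)
    if (spec$contamination_fraction > 0) {
      cspec <- spec
      cspec$species <- spec$contaminant_species
      cspec$copy_number_mean <- 0
      contam <- simulate_species_reads(cspec, refs, include_te = FALSE)
      mixed <- inject_contamination(main, contam,
                                    spec$contamination_fraction, seed = NULL)
      main <- mixed
    } else {
      main$truth$contamination_reads <- 0L
      main$truth$reads$contaminant <- rep(FALSE, nrow(main$truth$reads))
    }
    main$truth <- structure(main$truth, class = "truth_record")
    main
  })
}

## Generate the reads of one species' pool (SCGs always; TE if requested).
simulate_species_reads <- function(spec, refs, include_te = TRUE) {
  n <- spec$n_individuals
  rl <- spec$read_length
  cov_copy <- spec$depth / (2 * n)  # per haploid genome copy
  scg <- refs$scg[refs$scg$species == spec$species, , drop = FALSE]
  if (nrow(scg) == 0L) {
    stop("no SCG entries for species '", spec$species, "'", call. = FALSE)
  }
  sites <- as.integer(names(spec$allele_profile))
  del <- spec$deletion_interval
  del_len <- del[2] - del[1] + 1L

  te_copies <- if (!include_te || spec$copy_number_mean == 0) {
    rep(0L, n)
  } else if (spec$copy_number_dist == "fixed") {
    rep(as.integer(round(2 * spec$copy_number_mean)), n)
  } else {
    rpois(n, 2 * spec$copy_number_mean)
  }

  reads_ref <- character(0); reads_start <- integer(0)
  reads_seq <- character(0); reads_ind <- integer(0); reads_copy <- integer(0)
  copies_df <- list(); alleles_df <- list()

  ## SCG reads: two identical haplotypes per individual per gene
  for (g in seq_len(nrow(scg))) {
    gname <- paste(scg$gene[g], scg$species[g], sep = "|")
    for (ind in seq_len(n)) {
      rd <- draw_reads_from(scg$sequence[g], 2 * cov_copy, rl)
      if (nrow(rd)) {
        reads_ref <- c(reads_ref, rep(gname, nrow(rd)))
        reads_start <- c(reads_start, rd$start)
        reads_seq <- c(reads_seq, rd$seq)
        reads_ind <- c(reads_ind, rep(ind, nrow(rd)))
        reads_copy <- c(reads_copy, rep(NA_integer_, nrow(rd)))
      }
    }
  }

  ## TE reads: per-copy haplotype with profiled alleles, optional deletion
  copy_id <- 0L
  for (ind in seq_len(n)) {
    k <- te_copies[ind]
    if (k == 0L) next
    for (cp in seq_len(k)) {
      copy_id <- copy_id + 1L
      deleted <- spec$deletion_fraction > 0 &&
        runif(1) < spec$deletion_fraction
      copy_seq <- refs$te_sequence
      copy_alleles <- character(length(sites))
      for (si in seq_along(sites)) {
        fr <- spec$allele_profile[[si]]
        al <- sample(names(fr), 1L, prob = fr)
        copy_alleles[si] <- al
        substr(copy_seq, sites[si], sites[si]) <- al
      }
      copies_df[[copy_id]] <- data.frame(ind = ind, copy = copy_id,
                                         deleted = deleted)
      if (length(sites)) {
        alleles_df[[copy_id]] <- data.frame(ind = ind, copy = copy_id,
                                            site = sites,
                                            allele = copy_alleles)
      }
      if (deleted) {
        ## reads only from the two flanks, none spanning the junction
        left <- substr(copy_seq, 1L, del[1] - 1L)
        right <- substr(copy_seq, del[2] + 1L, nchar(copy_seq))
        for (part in list(list(seq = left, off = 0L),
                          list(seq = right, off = del[2]))) {
          rd <- draw_reads_from(part$seq, cov_copy, rl)
          if (nrow(rd)) {
            reads_ref <- c(reads_ref, rep(refs$te_name, nrow(rd)))
            reads_start <- c(reads_start, rd$start + part$off)
            reads_seq <- c(reads_seq, rd$seq)
            reads_ind <- c(reads_ind, rep(ind, nrow(rd)))
            reads_copy <- c(reads_copy, rep(copy_id, nrow(rd)))
          }
        }
      } else {
        rd <- draw_reads_from(copy_seq, cov_copy, rl)
        if (nrow(rd)) {
          reads_ref <- c(reads_ref, rep(refs$te_name, nrow(rd)))
          reads_start <- c(reads_start, rd$start)
          reads_seq <- c(reads_seq, rd$seq)
          reads_ind <- c(reads_ind, rep(ind, nrow(rd)))
          reads_copy <- c(reads_copy, rep(copy_id, nrow(rd)))
        }
      }
    }
  }

  reads_seq <- apply_errors(reads_seq, spec$error_rate)
  ids <- sprintf("r%06d|ind=%d|ref=%s|copy=%s|pos=%d|sp=%s",
                 seq_along(reads_seq), reads_ind, reads_ref,
                 ifelse(is.na(reads_copy), "scg", as.character(reads_copy)),
                 reads_start, spec$species)
  reads <- setNames(reads_seq, ids)

  truth <- list(
    individuals = data.frame(ind = seq_len(n), te_copies = te_copies),
    copies = if (length(copies_df)) do.call(rbind, copies_df) else
      data.frame(ind = integer(0), copy = integer(0), deleted = logical(0)),
    alleles = if (length(alleles_df)) do.call(rbind, alleles_df) else
      data.frame(ind = integer(0), copy = integer(0), site = integer(0),
                 allele = character(0)),
    reads = data.frame(id = ids, ind = reads_ind, ref = reads_ref,
                       copy = reads_copy, start = reads_start,
                       species = spec$species,
                       contaminant = FALSE, stringsAsFactors = FALSE),
    contamination_reads = 0L
  )
  list(reads = reads, truth = truth)
}

#' Mix contaminating reads into a pool
#'
#' Replaces a fraction of the reads of pool `a` by reads of pool `b`: the
#' output has the same total read count as `a`, of which exactly
#' `round(fraction * total)` are drawn (without replacement when possible)
#' from `b`.  Both arguments may be plain named character vectors of reads
#' or `simulate_pool()` results; in the latter case the truth records are
#' merged and contaminating reads flagged.
#'
#' @param reads_a Host pool (reads or `simulate_pool()` result).
#' @param reads_b Contaminant pool.
#' @param fraction Contaminating read fraction in \[0, 1\].
#' @param seed Optional seed for reproducible subsampling.
#' @return Same shape as `reads_a`.
#' @export
inject_contamination <- function(reads_a, reads_b, fraction, seed = NULL) {
  assert_scalar_number(fraction, "fraction", 0, 1)
  a_is_pool <- is.list(reads_a) && !is.null(reads_a$reads)
  b_is_pool <- is.list(reads_b) && !is.null(reads_b$reads)
  ra <- if (a_is_pool) reads_a$reads else reads_a
  rb <- if (b_is_pool) reads_b$reads else reads_b

  with_seed(seed, {
    total <- length(ra)
    n_b <- round(fraction * total)
    n_a <- total - n_b
    keep_a <- if (n_a == total) seq_len(total) else
      sort(sample.int(total, n_a))
    take_b <- if (n_b == 0L) {
      integer(0)
    } else if (fraction == 1) {
      seq_along(rb)  # a full swap keeps pool b's content exactly
    } else if (n_b <= length(rb)) {
      sort(sample.int(length(rb), n_b))
    } else {
      sample.int(length(rb), n_b, replace = TRUE)
    }
    out_reads <- c(ra[keep_a], rb[take_b])

    if (!a_is_pool) return(out_reads)

    truth <- reads_a$truth
    truth$reads <- truth$reads[keep_a, , drop = FALSE]
    truth$reads$contaminant <- rep(FALSE, nrow(truth$reads))
    if (b_is_pool && n_b > 0L) {
      tb <- reads_b$truth$reads[take_b, , drop = FALSE]
      tb$contaminant <- TRUE
      truth$reads <- rbind(truth$reads, tb)
    }
    truth$contamination_reads <- length(take_b)
    list(reads = out_reads, truth = truth)
  })
}

#' Tally truth allele fractions at a TE site
#'
#' Aggregates the per-copy allele assignments of a truth record into allele
#' fractions at one consensus site, optionally restricted to copies that do
#' not carry the internal deletion (the copies that actually emit reads
#' over a deleted site).
#'
#' @param truth A `truth_record` from [simulate_pool()].
#' @param site 1-based consensus site.
#' @param non_deleted_only Count only non-deleted copies (default `TRUE`).
#' @return Named numeric vector of allele fractions (empty if no copies).
#' @export
truth_allele_fractions <- function(truth, site, non_deleted_only = TRUE) {
  al <- truth$alleles[truth$alleles$site == site, , drop = FALSE]
  if (non_deleted_only && nrow(al)) {
    keep <- truth$copies$copy[!truth$copies$deleted]
    al <- al[al$copy %in% keep, , drop = FALSE]
  }
  if (!nrow(al)) return(numeric(0))
  tab <- table(al$allele)
  as.numeric(tab) / sum(tab) -> fr
  setNames(fr, names(tab))
}

#' Write reads to FASTQ
#'
#' Four-line records with a constant quality string (the pipeline uses no
#' quality information).
#'
#' @param reads Named character vector of read sequences.
#' @param path Output path.
#' @param quality_char Quality character used for every base.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path, quality_char = "I") {
  if (length(reads) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  qual <- vapply(nchar(reads), function(w)
    strrep(quality_char, w), "")
  rec <- rbind(paste0("@", names(reads)), unname(reads), "+", qual)
  writeLines(as.vector(rec), path)
  invisible(path)
}

#' Read a FASTQ file into a named character vector of reads
#'
#' @param path FASTQ path (uncompressed).
#' @return Named character vector of read sequences.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L) return(setNames(character(0), character(0)))
  if (length(lines) %% 4L != 0L) {
    stop("malformed FASTQ: line count not a multiple of 4", call. = FALSE)
  }
  ids <- sub("^@", "", lines[seq(1L, length(lines), by = 4L)])
  seqs <- lines[seq(2L, length(lines), by = 4L)]
  setNames(toupper(seqs), ids)
}
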