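#' Trim reads to a fixed length
#'
#' Reads longer than `target_length` are truncated from the 3' end; reads
#' shorter than `min_keep` are dropped; everything else passes unchanged.
#' Trimming all reads to a common length keeps per-position coverage
#' comparable across samples sequenced with different read lengths.
#'
#' @param reads Named character vector of read sequences.
#' @param target_length Length to trim to (default 100 bp).
#' @param min_keep Minimum read length to retain (default 1).
#' @return Named character vector of trimmed reads.
#' @export
trim_reads <- function(reads, target_length = 100L, min_keep = 1L) {
  target_length <- assert_count(target_length, "target_length", lower = 1L)
  min_keep <- assert_count(min_keep, "min_keep", lower = 1L)
  if (min_keep > target_length) {
    stop("`target_length` must be >= `min_keep`", call. = FALSE)
  }
  if (length(reads) == 0L) return(reads)
  w <- nchar(reads)
  keep <- w >= min_keep
  reads <- reads[keep]
  w <- w[keep]
  long <- w > target_length
  if (any(long)) {
    reads[long] <- substr(reads[long], 1L, target_length)
  }
  reads
}

## Build a seed index: environment mapping each k-mer to the matrix of
## (reference index, 1-based position) where it occurs.
build_seed_index <- function(seqs, k) {
  idx <- new.env(hash = TRUE, size = sum(nchar(seqs)))
  for (ri in seq_along(seqs)) {
    L <- nchar(seqs[[ri]])
    if (L < k) next
    starts <- seq_len(L - k + 1L)
    kmers <- substring(seqs[[ri]], starts, starts + k - 1L)
    for (j in seq_along(kmers)) {
      key <- kmers[j]
      hit <- idx[[key]]
      idx[[key]] <- if (is.null(hit)) cbind(ri, starts[j]) else
        rbind(hit, c(ri, starts[j]))
    }
  }
  idx
}

#' Align reads gaplessly to a reference set (seed-and-extend)
#'
#' A deliberately minimal internal aligner that makes synthetic tests
#' self-contained: the first `seed_length` bases of each read are looked up
#' exactly in a k-mer index of the references, and each candidate placement
#' is extended gaplessly over the full read.  A read is reported aligned at
#' the placement with the fewest mismatches if that placement is unique and
#' has at most `max_mismatches` mismatches; reads with no candidate or with
#' tied best placements are reported unaligned.  Production data should be
#' aligned with an external mapper and ingested as SAM via [read_sam()].
#'
#' @param reads Named character vector of reads.
#' @param refs A [reference_set()].
#' @param species Restrict the target to the TE plus this species' SCGs
#'   (`NULL` aligns against everything).
#' @param max_mismatches Maximum mismatches for a reported alignment.
#' @param seed_length Exact-match seed length; must not exceed the read
#'   length.
#' @return An object of class `alignments`: a data.frame with columns
#'   `id`, `ref` (NA when unaligned), `pos` (1-based), `seq`, `mismatches`.
#' @export
align_reads <- function(reads, refs, species = NULL,
                        max_mismatches = 3L, seed_length = 20L) {
  stopifnot(inherits(refs, "reference_set"))
  max_mismatches <- assert_count(max_mismatches, "max_mismatches")
  seed_length <- assert_count(seed_length, "seed_length", lower = 1L)
  target <- ref_sequences(refs, species)
  tlen <- nchar(target)
  if (length(reads) && seed_length > min(nchar(reads))) {
    stop("seed_length exceeds the shortest read length", call. = FALSE)
  }
  idx <- build_seed_index(target, seed_length)
  traw <- lapply(target, charToRaw)

  n <- length(reads)
  out_ref <- rep(NA_character_, n)
  out_pos <- rep(NA_integer_, n)
  out_mm <- rep(NA_integer_, n)
  if (n) {
    rl <- nchar(reads)
    rraw <- lapply(reads, charToRaw)
    for (i in seq_len(n)) {
      ## three seed offsets (start, middle, end) so a read is still placed
      ## when a variant or error falls inside one seed
      offs <- unique(c(0L, as.integer((rl[i] - seed_length) / 2),
                       rl[i] - seed_length))
      offs <- offs[offs >= 0L]
      cand <- NULL
      for (off in offs) {
        hit <- idx[[substr(reads[[i]], off + 1L, off + seed_length)]]
        if (!is.null(hit)) {
          hit[, 2L] <- hit[, 2L] - off
          cand <- rbind(cand, hit)
        }
      }
      if (is.null(cand)) next
      cand <- unique(cand[cand[, 2L] >= 1L, , drop = FALSE])
      if (nrow(cand) == 0L) next
      best_mm <- max_mismatches + 1L
      best_j <- 0L
      tie <- FALSE
      for (j in seq_len(nrow(cand))) {
        ri <- cand[j, 1L]; p <- cand[j, 2L]
        if (p + rl[i] - 1L > tlen[ri]) next  # would run past the end
        mm <- sum(rraw[[i]] != traw[[ri]][p:(p + rl[i] - 1L)])
        if (mm < best_mm) {
          best_mm <- mm; best_j <- j; tie <- FALSE
        } else if (mm == best_mm) {
          tie <- TRUE
        }
      }
      if (best_j > 0L && !tie && best_mm <= max_mismatches) {
        out_ref[i] <- names(target)[cand[best_j, 1L]]
        out_pos[i] <- cand[best_j, 2L]
        out_mm[i] <- best_mm
      }
    }
  }
  structure(
    data.frame(id = if (is.null(names(reads))) sprintf("r%06d", seq_len(n))
               else names(reads),
               ref = out_ref, pos = out_pos,
               seq = unname(as.character(reads)),
               mismatches = out_mm, stringsAsFactors = FALSE),
    class = c("alignments", "data.frame")
  )
}

#' Tally per-site nucleotide counts from alignments
#'
#' For every reference position, counts the aligned base of each read
#' covering it.  `N` bases never count toward any allele and do not
#' increment coverage; coverage is the sum of the four nucleotide counts.
#' Unaligned reads are ignored.  Alignments that would extend beyond the
#' reference end are rejected with a warning and counted in the
#' `n_rejected` attribute.
#'
#' @param alignments An `alignments` data.frame (from [align_reads()] or
#'   [read_sam()]).
#' @param refs A [reference_set()].
#' @param species Restrict output to the TE plus this species' SCGs.
#' @return A `site_counts` data.frame with columns `ref`, `pos`, `A`, `C`,
#'   `G`, `T`, `cov`, one row per reference position.
#' @export
pileup <- function(alignments, refs, species = NULL) {
  stopifnot(inherits(refs, "reference_set"))
  target <- ref_sequences(refs, species)
  tlen <- nchar(target)
  aln <- alignments[!is.na(alignments$ref), , drop = FALSE]
  unknown <- !(aln$ref %in% names(target))
  if (any(unknown)) {
    stop("alignments reference sequences absent from the reference set: ",
         paste(unique(aln$ref[unknown]), collapse = ", "), call. = FALSE)
  }
  too_far <- aln$pos + nchar(aln$seq) - 1L > tlen[aln$ref] | aln$pos < 1L
  n_rejected <- sum(too_far)
  if (n_rejected > 0L) {
    warning(n_rejected, " alignment(s) extend beyond the reference end; ",
            "rejected", call. = FALSE)
    aln <- aln[!too_far, , drop = FALSE]
  }

  ## skeleton of all positions
  counts <- data.frame(
    ref = rep(names(target), tlen),
    pos = unlist(lapply(tlen, seq_len), use.names = FALSE),
    A = 0L, C = 0L, G = 0L, T = 0L
  )
  if (nrow(aln)) {
    ex <- explode_bases(aln$seq)
    refpos <- aln$pos[ex$read] + ex$offset
    refname <- aln$ref[ex$read]
    keep <- ex$base %in% DNA_BASES
    if (any(keep)) {
      ri <- match(refname[keep], names(target))
      offset_ref <- cumsum(c(0L, tlen))[seq_along(target)]
      row <- offset_ref[ri] + refpos[keep]
      bi <- match(ex$base[keep], DNA_BASES)
      tab <- tabulate(4L * (row - 1L) + bi, nbins = 4L * sum(tlen))
      m <- matrix(tab, ncol = 4L, byrow = TRUE)
      counts$A <- m[, 1L]; counts$C <- m[, 2L]
      counts$G <- m[, 3L]; counts$T <- m[, 4L]
    }
  }
  counts$cov <- counts$A + counts$C + counts$G + counts$T
  structure(counts, class = c("site_counts", "data.frame"),
            n_rejected = n_rejected)
}

#' Write alignments as SAM
#'
#' Minimal SAM output for the gapless internal aligner: mapped reads get
#' flag 0 and a single `<len>M` CIGAR; unmapped reads get flag 4.
#'
#' @param alignments An `alignments` data.frame.
#' @param refs A [reference_set()] used for the `@SQ` header lines.
#' @param path Output path.
#' @param species Restrict `@SQ` lines to the TE plus this species' SCGs.
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, refs, path, species = NULL) {
  target <- ref_sequences(refs, species)
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(target), nchar(target)))
  mapped <- !is.na(alignments$ref)
  qual <- vapply(nchar(alignments$seq), strrep, "", x = "I")
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
                  alignments$id,
                  ifelse(mapped, 0L, 4L),
                  ifelse(mapped, alignments$ref, "*"),
                  ifelse(mapped, alignments$pos, 0L),
                  ifelse(mapped, 60L, 0L),
                  ifelse(mapped, paste0(nchar(alignments$seq), "M"), "*"),
                  alignments$seq, qual)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read gapless alignments from SAM
#'
#' Ingests externally produced alignments.  Only primary, mapped, gapless
#' records (CIGAR of the form `<len>M`, possibly with soft-clips which are
#' removed) are retained as aligned; everything else is reported unaligned.
#'
#' @param path SAM path (plain text).
#' @return An `alignments` data.frame as produced by [align_reads()].
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (length(lines) == 0L) {
    return(structure(
      data.frame(id = character(0), ref = character(0), pos = integer(0),
                 seq = character(0), mismatches = integer(0)),
      class = c("alignments", "data.frame")))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  get <- function(k) vapply(fields, `[`, "", k)
  id <- get(1L)
  flag <- as.integer(get(2L))
  ref <- get(3L)
  pos <- as.integer(get(4L))
  cigar <- get(6L)
  seq <- toupper(get(10L))
  ## drop secondary/supplementary records
  primary <- bitwAnd(flag, 256L) == 0L & bitwAnd(flag, 2048L) == 0L
  id <- id[primary]; flag <- flag[primary]; ref <- ref[primary]
  pos <- pos[primary]; cigar <- cigar[primary]; seq <- seq[primary]
  mapped <- bitwAnd(flag, 4L) == 0L & grepl("^[0-9]+M$", cigar)
  ref[!mapped] <- NA_character_
  pos[!mapped] <- NA_integer_
  structure(
    data.frame(id = id, ref = ref, pos = pos, seq = seq,
               mismatches = NA_integer_, stringsAsFactors = FALSE),
    class = c("alignments", "data.frame")
  )
}

#' Write and read per-site nucleotide counts as TSV
#'
#' @param counts A `site_counts` data.frame.
#' @param path TSV path.
#' @return `path` (write) or a `site_counts` data.frame (read).
#' @export
write_site_counts <- function(counts, path) {
  write.table(as.data.frame(counts), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_site_counts
#' @export
read_site_counts <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("ref", "pos", "A", "C", "G", "T", "cov") %in% names(df)))
  structure(df, class = c("site_counts", "data.frame"))
}
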