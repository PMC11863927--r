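#' Reference set: TE consensus plus single-copy-gene orthologs
#'
#' The alignment and normalization target of the pipeline: one transposable
#' element (TE) consensus sequence plus the single-copy-gene (SCG) ortholog
#' sequences of each species.  TE coverage is converted to copy number by
#' normalizing to the SCG coverage, so the SCGs calibrate the per-haploid
#' sequencing depth of each sample.
#'
#' @param te_name Name of the TE consensus sequence.
#' @param te_sequence TE consensus sequence (single character string,
#'   alphabet ACGTN).
#' @param scg A data.frame with columns `gene`, `species`, `sequence`:
#'   one row per SCG ortholog.  `gene` x `species` must be unique.
#'
#' @return An object of class `reference_set` with elements `te_name`,
#'   `te_sequence` and `scg`.
#' @export
#' @examples
#' refs <- reference_set("TE", "ACGTACGTAC",
#'   data.frame(gene = "g1", species = "melanogaster", sequence = "ACGTACGT"))
#' ref_names(refs)
reference_set <- function(te_name, te_sequence, scg) {
  stopifnot(is.character(te_name), length(te_name) == 1L,
            is.character(te_sequence), length(te_sequence) == 1L,
            is.data.frame(scg),
            all(c("gene", "species", "sequence") %in% names(scg)))
  te_sequence <- toupper(te_sequence)
  scg$sequence <- toupper(scg$sequence)
  seqs <- c(te_sequence, scg$sequence)
  if (any(nchar(seqs) == 0L)) {
    stop("all reference sequences must be non-empty", call. = FALSE)
  }
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop("reference sequences must use alphabet {A,C,G,T,N}", call. = FALSE)
  }
  key <- paste(scg$gene, scg$species, sep = "|")
  if (anyDuplicated(key)) {
    stop("gene x species combinations must be unique in the SCG table",
         call. = FALSE)
  }
  structure(
    list(te_name = te_name, te_sequence = te_sequence,
         scg = scg[, c("gene", "species", "sequence")]),
    class = "reference_set"
  )
}

#' Read a reference set from FASTA
#'
#' SCG records are identified by a FASTA header of the form
#' `gene|species`; the single remaining record (or the one named by
#' `te_name`) is taken as the TE consensus.
#'
#' @param fasta Path to a FASTA file.
#' @param te_name Optional name of the TE record; defaults to the record
#'   whose header contains no `|` separator.
#' @return A [reference_set()].
#' @export
read_reference_set <- function(fasta, te_name = NULL) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  nm <- sub("\\s.*$", "", names(seqs))
  is_scg <- grepl("|", nm, fixed = TRUE)
  if (is.null(te_name)) {
    if (sum(!is_scg) != 1L) {
      stop("expected exactly one TE record (header without '|'); ",
           "pass `te_name` to disambiguate", call. = FALSE)
    }
    te_idx <- which(!is_scg)
  } else {
    te_idx <- match(te_name, nm)
    if (is.na(te_idx)) stop("TE record '", te_name, "' not found", call. = FALSE)
  }
  scg_idx <- setdiff(which(is_scg), te_idx)
  parts <- strsplit(nm[scg_idx], "|", fixed = TRUE)
  scg <- data.frame(
    gene = vapply(parts, `[`, "", 1L),
    species = vapply(parts, `[`, "", 2L),
    sequence = as.character(seqs[scg_idx]),
    stringsAsFactors = FALSE
  )
  reference_set(nm[te_idx], as.character(seqs[te_idx]), scg)
}

#' Write a reference set to FASTA
#'
#' SCG headers are written as `gene|species` so the file round-trips
#' through [read_reference_set()].
#'
#' @param refs A [reference_set()].
#' @param fasta Output path.
#' @return `fasta`, invisibly.
#' @export
write_reference_set <- function(refs, fasta) {
  stopifnot(inherits(refs, "reference_set"))
  seqs <- Biostrings::DNAStringSet(c(refs$te_sequence, refs$scg$sequence))
  names(seqs) <- c(refs$te_name,
                   paste(refs$scg$gene, refs$scg$species, sep = "|"))
  Biostrings::writeXStringSet(seqs, fasta)
  invisible(fasta)
}

#' Sequences of a reference set restricted to one species
#'
#' Returns the named character vector of reference sequences a sample of
#' `species` is aligned against: the TE consensus plus that species' SCGs.
#' SCG names are `gene|species`.
#'
#' @param refs A [reference_set()].
#' @param species Species label, or `NULL` for all species' SCGs.
#' @return Named character vector of sequences.
#' @export
ref_sequences <- function(refs, species = NULL) {
  stopifnot(inherits(refs, "reference_set"))
  scg <- refs$scg
  if (!is.null(species)) {
    scg <- scg[scg$species %in% species, , drop = FALSE]
    if (nrow(scg) == 0L) {
      stop("no SCG entries for species '", paste(species, collapse = ","),
           "'", call. = FALSE)
    }
  }
  out <- c(refs$te_sequence, scg$sequence)
  names(out) <- c(refs$te_name, paste(scg$gene, scg$species, sep = "|"))
  out
}

#' @rdname ref_sequences
#' @export
ref_names <- function(refs, species = NULL) {
  names(ref_sequences(refs, species))
}

scg_names <- function(refs, species) {
  scg <- refs$scg[refs$scg$species %in% species, , drop = FALSE]
  if (nrow(scg) == 0L) {
    stop("no SCG entries for species '", species, "'", call. = FALSE)
  }
  paste(scg$gene, scg$species, sep = "|")
}

#' @export
print.reference_set <- function(x, ...) {
  cat("reference_set:", x$te_name,
      sprintf("(%d bp)", nchar(x$te_sequence)), "\n")
  cat("  SCGs:", nrow(x$scg), "entries,",
      length(unique(x$scg$species)), "species\n")
  invisible(x)
}
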