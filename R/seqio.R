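#' Read a FASTA file into a sequence table
#'
#' Sequences are upper-cased and RNA `U` residues are mapped to DNA `T`. The
#' first whitespace-delimited token of each header is the record id; the rest
#' is kept as the description.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id`, `residues`, `description`, one row per
#'   record, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) abort(sprintf("empty FASTA file: %s", path))
  headers <- names(set)
  id <- sub("\\s.*$", "", headers)
  description <- ifelse(grepl("\\s", headers),
                        sub("^\\S+\\s+", "", headers), "")
  dup <- unique(id[duplicated(id)])
  if (length(dup) > 0) {
    abort(sprintf("duplicate sequence id(s) in %s: %s",
                  path, paste(dup, collapse = ", ")))
  }
  residues <- normalize_residues(as.character(set))
  check_nucleotides(residues, sprintf("FASTA file %s", path))
  if (any(nchar(residues) == 0)) abort(sprintf("empty sequence record in %s", path))
  tibble(id = unname(id), residues = unname(residues),
         description = unname(description))
}

#' Write a sequence table to FASTA
#'
#' @param records Tibble with columns `id`, `residues` and optionally
#'   `description`. An empty table writes an empty file.
#' @param path Output path.
#' @param wrap Line width for sequence wrapping (default 60 columns).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, wrap = 60) {
  stopifnot(wrap >= 1)
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(records) == 0) return(invisible(path))
  desc <- if ("description" %in% names(records)) records$description else ""
  for (i in seq_len(nrow(records))) {
    header <- if (nzchar(desc[[i]] %||% "")) {
      paste0(">", records$id[[i]], " ", desc[[i]])
    } else {
      paste0(">", records$id[[i]])
    }
    seq <- records$residues[[i]]
    starts <- seq(1, nchar(seq), by = wrap)
    writeLines(c(header, substring(seq, starts, pmin(starts + wrap - 1, nchar(seq)))), con)
  }
  invisible(path)
}

#' Read a tRNA reference library
#'
#' Reads genomic tRNA sequences from FASTA. An optional intron is annotated in
#' the record description as `intron=<start>-<end>` (0-based half-open, on the
#' unspliced sequence). The spliced (intron-removed) sequence and the mature
#' sequence are derived; the mature form is the spliced sequence with the
#' post-transcriptional `CCA` appended when the record does not already end in
#' `CCA`.
#'
#' @param path Path to a FASTA file of tRNA genes.
#' @return A tibble with columns `id`, `residues`, `description`,
#'   `intron_start`, `intron_end` (NA when intron-less), `spliced`, `mature`.
#' @export
read_trna_library <- function(path) {
  recs <- read_fasta(path)
  m <- stringr::str_match(recs$description, "intron=(\\d+)-(\\d+)")
  intron_start <- suppressWarnings(as.integer(m[, 2]))
  intron_end <- suppressWarnings(as.integer(m[, 3]))
  spliced <- recs$residues
  for (i in seq_len(nrow(recs))) {
    if (!is.na(intron_start[i])) {
      len <- nchar(recs$residues[i])
      if (intron_start[i] < 0 || intron_end[i] > len || intron_start[i] >= intron_end[i]) {
        abort(sprintf("intron interval [%d,%d) outside sequence %s (length %d)",
                      intron_start[i], intron_end[i], recs$id[i], len))
      }
      spliced[i] <- paste0(substr0(recs$residues[i], 0, intron_start[i]),
                           substr0(recs$residues[i], intron_end[i], len))
    }
  }
  mature <- ifelse(endsWith(spliced, "CCA"), spliced, paste0(spliced, "CCA"))
  mutate(recs, intron_start = intron_start, intron_end = intron_end,
         spliced = spliced, mature = mature)
}

#' Read a repeat family library
#'
#' Supports two conventions, which may be mixed in one file: (a) a single
#' record holding a full-length consensus, and (b) the split convention where
#' family `X` is stored as record `X` (the LTR consensus) plus record `X-I`
#' (the internal-portion consensus); the full consensus is then reconstructed
#' as LTR + internal + LTR.
#'
#' @param path Path to a FASTA family library.
#' @return A list of [trim_family] objects, named by family id.
#' @export
read_family_library <- function(path) {
  recs <- read_fasta(path)
  internal_ids <- recs$id[grepl("-I$", recs$id)]
  fams <- list()
  for (iid in internal_ids) {
    base <- sub("-I$", "", iid)
    if (!base %in% recs$id) {
      abort(sprintf("internal record %s present without LTR record %s", iid, base))
    }
    ltr <- recs$residues[recs$id == base]
    internal <- recs$residues[recs$id == iid]
    fams[[base]] <- trim_family(
      family_id = base,
      consensus = paste0(ltr, internal, ltr),
      ltr_len = nchar(ltr)
    )
  }
  singles <- recs$id[!recs$id %in% c(internal_ids, sub("-I$", "", internal_ids))]
  for (sid in singles) {
    fams[[sid]] <- trim_family(family_id = sid,
                               consensus = recs$residues[recs$id == sid])
  }
  fams[recs$id[recs$id %in% names(fams)]]
}

#' Construct a repeat family model
#'
#' A family model carries the consensus sequence and, when known, its
#' partition into 5' LTR, internal portion and 3' LTR (the two LTRs have equal
#' length and tile the consensus with the internal region), the family class
#' and the target-site-duplication length.
#'
#' @param family_id Family name.
#' @param consensus Consensus nucleotide string.
#' @param ltr_len LTR length in bp, or `NA` when the partition is unknown.
#' @param family_class One of `"TRIMp2"`, `"TRIMp3_tRNA"`, `"TRIMp3_5S"`,
#'   `"unclassified"`.
#' @param tsd_len Target-site-duplication length (4-6), or `NA`.
#' @param ltr_identity Identity between the two LTR copies, or `NA`.
#' @param copies Optional tibble of genomic copies backing the consensus.
#' @param complete Whether both element termini were located.
#' @return An object of class `trim_family`.
#' @export
trim_family <- function(family_id, consensus, ltr_len = NA_integer_,
                        family_class = "unclassified", tsd_len = NA_integer_,
                        ltr_identity = NA_real_, copies = NULL,
                        complete = !is.na(ltr_len)) {
  consensus <- normalize_residues(consensus)
  check_nucleotides(consensus, sprintf("family %s consensus", family_id))
  len <- nchar(consensus)
  if (!is.na(ltr_len) && 2 * ltr_len > len) {
    abort(sprintf("family %s: twice the LTR length (%d) exceeds the consensus length (%d)",
                  family_id, ltr_len, len))
  }
  structure(
    list(family_id = family_id, consensus = consensus,
         ltr_len = as.integer(ltr_len), family_class = family_class,
         tsd_len = as.integer(tsd_len), ltr_identity = ltr_identity,
         copies = copies, complete = isTRUE(complete)),
    class = "trim_family"
  )
}

#' @export
print.trim_family <- function(x, ...) {
  cat(sprintf("<trim_family> %s: %d bp, class %s\n",
              x$family_id, nchar(x$consensus), x$family_class))
  if (!is.na(x$ltr_len)) {
    cat(sprintf("  LTRs %d bp, internal %d bp, TSD %s bp\n", x$ltr_len,
                nchar(x$consensus) - 2L * x$ltr_len,
                ifelse(is.na(x$tsd_len), "?", x$tsd_len)))
  }
  invisible(x)
}

# LTR / internal intervals (0-based half-open) of a partitioned family
family_partition <- function(family) {
  if (is.na(family$ltr_len)) abort(sprintf("family %s is not partitioned", family$family_id))
  len <- nchar(family$consensus)
  list(ltr5 = c(0L, family$ltr_len),
       internal = c(family$ltr_len, len - family$ltr_len),
       ltr3 = c(len - family$ltr_len, len))
}

#' LTR and internal consensus of a partitioned family
#'
#' @param family A [trim_family] with known partition.
#' @return A list with elements `ltr` and `internal` (nucleotide strings).
#' @export
family_parts <- function(family) {
  p <- family_partition(family)
  list(ltr = substr0(family$consensus, p$ltr5[1], p$ltr5[2]),
       internal = substr0(family$consensus, p$internal[1], p$internal[2]))
}

#' @export
#' @method tidy trim_family
tidy.trim_family <- function(x, ...) {
  tibble(family_id = x$family_id,
         length = nchar(x$consensus),
         ltr_len = x$ltr_len,
         internal_len = ifelse(is.na(x$ltr_len), NA_integer_,
                               nchar(x$consensus) - 2L * x$ltr_len),
         ltr_identity = x$ltr_identity,
         family_class = x$family_class,
         tsd_len = x$tsd_len,
         complete = x$complete)
}

#' Write structural annotations as GFF3
#'
#' Takes a feature table in the package's 0-based half-open convention and
#' writes GFF3 (1-based inclusive). Feature types used by the pipeline are
#' `LTR_retrotransposon` (parent feature), `long_terminal_repeat`,
#' `target_site_duplication`, `primer_binding_site` and `RR_tract` (the PPT).
#'
#' @param features Tibble with columns `seq_id`, `type`, `start`, `end`,
#'   `strand`, `id` and optionally `parent`. An empty table writes a
#'   header-only file.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(features, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(features) == 0) return(invisible(path))
  parent <- if ("parent" %in% names(features)) features$parent else NA_character_
  attrs <- ifelse(is.na(parent) | parent == "",
                  paste0("ID=", features$id),
                  paste0("ID=", features$id, ";Parent=", parent))
  lines <- paste(features$seq_id, "trimscan", features$type,
                 features$start + 1L, features$end, ".", features$strand, ".",
                 attrs, sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Read a GFF3 file back into the package's feature convention
#'
#' Minimal reader for round-tripping the files written by [write_gff3()]:
#' coordinates are converted back to 0-based half-open.
#'
#' @param path Path to a GFF3 file.
#' @return Tibble with columns `seq_id`, `type`, `start`, `end`, `strand`, `id`.
#' @export
read_gff3 <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble(seq_id = character(), type = character(),
                  start = integer(), end = integer(),
                  strand = character(), id = character()))
  }
  f <- do.call(rbind, strsplit(lines, "\t", fixed = TRUE))
  tibble(seq_id = f[, 1], type = f[, 3],
         start = as.integer(f[, 4]) - 1L, end = as.integer(f[, 5]),
         strand = f[, 7],
         id = sub("^ID=([^;]*).*$", "\\1", f[, 9]))
}
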