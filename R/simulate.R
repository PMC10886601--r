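# Synthetic genomes with planted TRIM/TRIMp3 elements and a complete truth
# table. The generator is first-class: every pipeline stage is validated
# against it. Backgrounds are i.i.d. nucleotides (GC configurable); copies
# descend from a single ancestor per family (star phylogeny) with per-copy
# substitutions and short indels; a configurable fraction of copies is
# collapsed to solo LTRs by LTR-LTR recombination that preserves the
# original TSD pair.

#' Specification of a synthetic TRIM family
#'
#' @param family_id Family name.
#' @param ltr_len LTR length (80-400 bp).
#' @param internal_len Internal-portion length (50-700 bp).
#' @param promoter Promoter planted in the LTR: `"none"`, `"tRNA_type2"`, or
#'   `"fiveS_type1"`.
#' @param pbs_mode PBS priming mode: `"three_prime_end"` or
#'   `"anticodon_loop"`.
#' @param pbs_trna_id Id of the priming tRNA in the library handed to
#'   [make_family()].
#' @param tsd_len Target-site-duplication length (4-6 bp).
#' @param copy_count Number of planted copies.
#' @param divergence Per-site substitution probability applied per copy.
#' @param indel_prob Per-site indel event probability (default one fifth of
#'   the substitution rate; events are 1-3 nt).
#' @param solo_fraction Probability that a copy is recombined into a solo LTR.
#' @param seed Seed controlling the family's ancestral sequence.
#' @return A `family_spec` list.
#' @export
family_spec <- function(family_id, ltr_len, internal_len,
                        promoter = c("none", "tRNA_type2", "fiveS_type1"),
                        pbs_mode = c("three_prime_end", "anticodon_loop"),
                        pbs_trna_id = NULL, tsd_len = 5, copy_count = 10,
                        divergence = 0.02, indel_prob = 0.2 * divergence,
                        solo_fraction = 0, seed = 1) {
  promoter <- match.arg(promoter)
  pbs_mode <- match.arg(pbs_mode)
  stopifnot(ltr_len >= 80, ltr_len <= 400,
            internal_len >= 50, internal_len <= 700,
            tsd_len >= 4, tsd_len <= 6,
            divergence >= 0, divergence <= 1,
            indel_prob >= 0, indel_prob <= 1,
            solo_fraction >= 0, solo_fraction <= 1,
            copy_count >= 1)
  structure(list(family_id = family_id, ltr_len = as.integer(ltr_len),
                 internal_len = as.integer(internal_len), promoter = promoter,
                 pbs_mode = pbs_mode, pbs_trna_id = pbs_trna_id,
                 tsd_len = as.integer(tsd_len),
                 copy_count = as.integer(copy_count),
                 divergence = divergence, indel_prob = indel_prob,
                 solo_fraction = solo_fraction, seed = as.integer(seed)),
            class = "family_spec")
}

random_dna <- function(n, gc = 0.5) {
  if (n == 0) return("")
  codes <- sample(c(65L, 84L, 71L, 67L), n, replace = TRUE,   # A T G C
                  prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2))
  intToUtf8(codes)
}

sample_iupac <- function(pattern) {
  paste(map_chr(chars(pattern), ~ sample(iupac_class[[.x]], 1)), collapse = "")
}

#' Synthetic tRNA reference library
#'
#' Generates a deterministic library of synthetic tRNA genes in the layout
#' produced by [read_trna_library()]: eight isoacceptors of 76 nt, four of
#' which carry a 14 nt intron after the anticodon (annotated
#' `intron=38-52`). None of the genes ends in CCA, so the mature form is the
#' spliced sequence plus the post-transcriptional CCA.
#'
#' @param seed Seed controlling the sequences.
#' @return A tibble in the [read_trna_library()] layout.
#' @export
synthetic_trna_library <- function(seed = 421) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  ids <- c("tRNA-Lys", "tRNA-Leu", "tRNA-His", "tRNA-Thr",
           "tRNA-iMet", "tRNA-Tyr", "tRNA-Ile", "tRNA-Asp")
  has_intron <- c(rep(FALSE, 4), rep(TRUE, 4))
  rows <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    body <- random_dna(76)
    # avoid an accidental genomic CCA terminus so the mature rule is exercised
    if (endsWith(body, "CCA")) body <- paste0(substr(body, 1, 73), "GTT")
    if (has_intron[i]) {
      gene <- paste0(substr0(body, 0, 38), random_dna(14), substr0(body, 38, 76))
      desc <- "synthetic tRNA gene intron=38-52"
      istart <- 38L; iend <- 52L
    } else {
      gene <- body
      desc <- "synthetic tRNA gene"
      istart <- NA_integer_; iend <- NA_integer_
    }
    rows[[i]] <- tibble(id = ids[i], residues = gene, description = desc,
                        intron_start = istart, intron_end = iend,
                        spliced = body, mature = paste0(body, "CCA"))
  }
  bind_rows(rows)
}

#' Build the ancestral element of a synthetic family
#'
#' The ancestor is LTR + internal + LTR with both LTRs identical. The LTR
#' embeds the requested pol III promoter boxes at randomized but recorded
#' offsets; the internal portion begins with a PBS complementary to the
#' chosen tRNA in the chosen mode and ends with a purine-rich PPT of at
#' least 10 nt.
#'
#' @param spec A [family_spec()].
#' @param trna_library tRNA table (e.g. [synthetic_trna_library()]).
#' @return A list with `spec`, `element`, `ltr`, `internal` and `meta`
#'   (planted box/PBS/PPT offsets).
#' @export
make_family <- function(spec, trna_library = synthetic_trna_library()) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  ltr <- chars(random_dna(spec$ltr_len))
  meta <- list()
  if (spec$promoter == "tRNA_type2") {
    # box A (TRGCY + 2-8 nt + YGG) and box B (GGTTC) 25-55 nt downstream
    linker <- sample(2:8, 1)
    a_len <- 5L + linker + 3L
    b_from_a <- sample(max(25L, a_len + 1L):min(55L, spec$ltr_len - 5L - 5L), 1)
    need <- max(a_len, b_from_a + 5L)
    if (spec$ltr_len < need + 5L) {
      abort(sprintf("family %s: tRNA-type promoter boxes do not fit in a %d bp LTR",
                    spec$family_id, spec$ltr_len))
    }
    a <- sample(0:(spec$ltr_len - need - 1L), 1)
    boxA1 <- sample_iupac("TRGCY"); boxA2 <- sample_iupac("YGG")
    ltr[(a + 1):(a + 5)] <- chars(boxA1)
    ltr[(a + 5 + linker + 1):(a + 5 + linker + 3)] <- chars(boxA2)
    b <- a + b_from_a
    ltr[(b + 1):(b + 5)] <- chars("GGTTC")
    meta$boxA <- c(a, a + a_len); meta$boxB <- c(b, b + 5L)
  } else if (spec$promoter == "fiveS_type1") {
    motifs <- default_5s_motifs()
    ga <- sample(motifs$gap_a_ie[1]:motifs$gap_a_ie[2], 1)
    gc_ <- sample(motifs$gap_ie_c[1]:motifs$gap_ie_c[2], 1)
    la <- nchar(motifs$boxA); li <- nchar(motifs$ie); lc <- nchar(motifs$boxC)
    total <- la + ga + li + gc_ + lc
    if (spec$ltr_len < total + 2L) {
      abort(sprintf("family %s: 5S promoter boxes do not fit in a %d bp LTR",
                    spec$family_id, spec$ltr_len))
    }
    a <- sample(0:(spec$ltr_len - total - 1L), 1)
    block <- paste0(sample_iupac(motifs$boxA), random_dna(ga),
                    sample_iupac(motifs$ie), random_dna(gc_),
                    sample_iupac(motifs$boxC))
    ltr[(a + 1):(a + total)] <- chars(block)
    meta$boxA <- c(a, a + la)
    meta$IE <- c(a + la + ga, a + la + ga + li)
    meta$boxC <- c(a + total - lc, a + total)
  }
  ltr <- paste(ltr, collapse = "")
  # PBS at the internal 5' end
  trna_id <- spec$pbs_trna_id %||% trna_library$id[1]
  tr <- trna_library[trna_library$id == trna_id, ]
  if (nrow(tr) != 1) abort(sprintf("tRNA %s not found in library", trna_id))
  if (spec$pbs_mode == "three_prime_end") {
    pbs_len <- 12L
    pbs <- revcomp(substr0(tr$mature, nchar(tr$mature) - pbs_len, nchar(tr$mature)))
  } else {
    # anticodon-loop priming pairs across the anticodon stem-loop
    # (spliced positions [27,43), 16 nt spanning the loop)
    pbs <- revcomp(substr0(tr$spliced, 27, 43))
    pbs_len <- nchar(pbs)
  }
  ppt <- paste(sample(c("A", "G"), 12, replace = TRUE), collapse = "")
  mid_len <- spec$internal_len - pbs_len - nchar(ppt)
  if (mid_len < 0) {
    abort(sprintf("family %s: internal length %d too short for PBS and PPT",
                  spec$family_id, spec$internal_len))
  }
  internal <- paste0(pbs, random_dna(mid_len), ppt)
  meta$pbs <- list(trna_id = trna_id, mode = spec$pbs_mode,
                   interval = c(0L, pbs_len))
  meta$ppt <- c(spec$internal_len - nchar(ppt), spec$internal_len)
  list(spec = spec, element = paste0(ltr, internal, ltr),
       ltr = ltr, internal = internal, meta = meta)
}

# per-copy mutation: substitutions at `divergence` per site, indel events
# (1-3 nt) at `indel_prob` per site; returns the sequence and event count
mutate_seq <- function(seq, divergence, indel_prob) {
  cs <- chars(seq)
  n <- length(cs)
  n_mut <- 0L
  if (divergence > 0) {
    hit <- which(stats::runif(n) < divergence)
    for (i in hit) cs[i] <- sample(setdiff(c("A", "C", "G", "T"), cs[i]), 1)
    n_mut <- n_mut + length(hit)
  }
  seq <- paste(cs, collapse = "")
  if (indel_prob > 0) {
    k <- stats::rbinom(1, n, indel_prob)
    if (k > 0) {
      pos <- sort(sample.int(nchar(seq), k), decreasing = TRUE)
      for (p in pos) {
        size <- sample(1:3, 1)
        if (stats::runif(1) < 0.5) {
          seq <- paste0(substr0(seq, 0, p), random_dna(size),
                        substr0(seq, p, nchar(seq)))
        } else {
          seq <- paste0(substr0(seq, 0, max(0, p - size)),
                        substr0(seq, p, nchar(seq)))
        }
      }
      n_mut <- n_mut + k
    }
  }
  list(seq = seq, n_mut = n_mut)
}

#' Plant synthetic families into a random genome
#'
#' Generates an i.i.d. background genome and integrates every copy of every
#' family at non-overlapping positions: the copy receives copy-specific
#' substitutions and indels, a 4-6 bp target sequence is duplicated to both
#' flanks (the TSD), a random strand is chosen, and with probability
#' `solo_fraction` the copy is collapsed to a single LTR that retains the
#' original TSD pair (LTR-LTR recombination).
#'
#' @param genome_len Background genome length (bp).
#' @param families List of [family_spec()]s (or a single spec).
#' @param seed Seed for the background, placements and mutations.
#' @param trna_library tRNA table used for the PBS of each ancestor.
#' @param gc Background GC content.
#' @param seq_id Name of the generated genome record.
#' @return A list with `genome` (sequence table), `truth` (tibble:
#'   `family_id`, `copy_id`, `seq_id`, `start`, `end`, `strand`, `is_solo`,
#'   `tsd`, `mutations`), and `ancestors` (sequence table of ancestral
#'   elements).
#' @export
plant_elements <- function(genome_len, families, seed = 1,
                           trna_library = synthetic_trna_library(),
                           gc = 0.5, seq_id = "chr1") {
  if (inherits(families, "family_spec")) families <- list(families)
  built <- map(families, make_family, trna_library = trna_library)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  total_planted <- sum(map_dbl(built, ~ nchar(.x$element) * .x$spec$copy_count))
  if (total_planted >= 0.5 * genome_len) {
    abort("total planted length must stay below half the genome length")
  }
  bg <- random_dna(genome_len, gc)
  # draw all insertions first (original background coordinates)
  ins <- list()
  for (f in built) {
    sp <- f$spec
    for (ci in seq_len(sp$copy_count)) {
      is_solo <- stats::runif(1) < sp$solo_fraction
      src <- if (is_solo) f$ltr else f$element
      mut <- mutate_seq(src, sp$divergence, sp$indel_prob)
      ins[[length(ins) + 1]] <- list(
        family_id = sp$family_id, copy_id = sprintf("%s_c%02d", sp$family_id, ci),
        seq = mut$seq, n_mut = mut$n_mut, is_solo = is_solo,
        strand = sample(c("+", "-"), 1), tsd_len = sp$tsd_len
      )
    }
  }
  # non-overlapping target positions with a small spacing margin
  margin <- 30L
  pos <- integer(0)
  for (i in seq_along(ins)) {
    ok <- FALSE
    for (try in 1:1000) {
      p <- sample.int(genome_len - 2L * margin, 1) + margin
      if (all(abs(p - pos) > margin)) { ok <- TRUE; break }
    }
    if (!ok) abort("could not place all elements without overlap; enlarge the genome")
    pos <- c(pos, p)
  }
  ord <- order(pos)
  ins <- ins[ord]; pos <- pos[ord]
  pieces <- character(0)
  truth <- vector("list", length(ins))
  cursor <- 0L
  offset <- 0L
  for (i in seq_along(ins)) {
    x <- ins[[i]]
    p <- pos[i]; t <- x$tsd_len
    tsd <- substr0(bg, p, p + t)
    emitted <- if (x$strand == "-") revcomp(x$seq) else x$seq
    pieces <- c(pieces, substr0(bg, cursor, p + t), emitted)
    start <- p + t + offset
    truth[[i]] <- tibble(
      family_id = x$family_id, copy_id = x$copy_id, seq_id = seq_id,
      start = as.integer(start), end = as.integer(start + nchar(emitted)),
      strand = x$strand, is_solo = x$is_solo, tsd = tsd,
      mutations = as.integer(x$n_mut)
    )
    offset <- offset + nchar(emitted) + t
    cursor <- p
  }
  pieces <- c(pieces, substr0(bg, cursor, genome_len))
  genome <- tibble(id = seq_id, residues = paste(pieces, collapse = ""),
                   description = "synthetic genome with planted TRIM elements")
  ancestors <- tibble(id = map_chr(built, ~ .x$spec$family_id),
                      residues = map_chr(built, "element"),
                      description = "planted ancestral element")
  list(genome = genome, truth = bind_rows(truth), ancestors = ancestors,
       families = built)
}
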