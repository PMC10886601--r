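# End-to-end discovery: scan -> cluster -> consensus/extend -> annotate ->
# classify -> count, mirroring the workflow used to build TRIM repeat
# libraries from genome assemblies.

#' Pipeline configuration
#'
#' All tunables of the discovery pipeline with their defaults: clustering at
#' 75% coverage / 75% identity, 500 bp flank extension, 4-6 bp TSDs, strict
#' >90%/>90% full-length counting.
#'
#' @param flank Flank (bp) re-extracted around copies per elongation round.
#' @param max_rounds Maximum elongation rounds.
#' @param max_members Copies used per round / per consensus.
#' @param cluster_min_coverage,cluster_min_identity Family clustering
#'   thresholds.
#' @param scan_min_identity,scan_min_length,seed_k Genome-scan parameters.
#' @param min_ltr,max_ltr,min_ltr_identity LTR-pair detection parameters.
#' @param full_length_frac,full_identity Full-length counting thresholds
#'   (strict inequalities).
#' @param min_cluster_size Smallest cluster carried into consensus building.
#' @param bootstrap_n Bootstrap replicates for optional promoter trees.
#' @param motif_config Optional path to a 5S motif configuration file.
#' @return A `discover_config` list.
#' @export
discover_config <- function(flank = 500, max_rounds = 10, max_members = 10,
                            cluster_min_coverage = 0.75,
                            cluster_min_identity = 0.75,
                            scan_min_identity = 0.6, scan_min_length = 30,
                            seed_k = 11, min_ltr = 80, max_ltr = 400,
                            min_ltr_identity = 0.8,
                            full_length_frac = 0.9, full_identity = 0.9,
                            min_cluster_size = 2, bootstrap_n = 100,
                            motif_config = NULL) {
  structure(as.list(environment()), class = "discover_config")
}

#' Run the full TRIM discovery pipeline
#'
#' Scans the genome with every seed sequence, pools the hit copies, clusters
#' them into families at the configured coverage/identity thresholds, builds
#' a majority-rule consensus per cluster and extends it to the element
#' termini, annotates the structure (LTR pair, TSD, PBS, PPT, pol III
#' promoter boxes), classifies each family as TRIMp2/TRIMp3, and counts
#' full-length LTR/internal copies and solo LTRs.
#'
#' @param genome Sequence table of the genome to annotate.
#' @param seeds Sequence table of seed/query sequences (known elements or
#'   representative copies).
#' @param trna_library Optional tRNA table; when `NULL` the PBS stage is
#'   skipped with a warning.
#' @param config A [discover_config()].
#' @return A `trim_discovery` object: list with `families` (list of
#'   [trim_family]), `annotations` (list of `trim_annotation`), `counts`,
#'   `solo`, `hits`, `clusters` and `config`. Use [tidy()] for the combined
#'   per-family table.
#' @export
run_discover <- function(genome, seeds, trna_library = NULL,
                         config = discover_config()) {
  motifs <- if (is.null(config$motif_config)) default_5s_motifs() else
    read_motif_config(config$motif_config)
  if (is.null(trna_library)) {
    warn("no tRNA library supplied; PBS detection will be skipped")
  }
  target_cache <- new.env(parent = emptyenv())
  hits <- bind_rows(map(seq_len(nrow(seeds)), function(i) {
    scan_genome(genome, setNames(seeds$residues[i], seeds$id[i]),
                min_identity = config$scan_min_identity,
                min_length = config$scan_min_length, seed_k = config$seed_k,
                .cache = target_cache)
  }))
  if (nrow(hits) == 0) {
    abort("discovery stage 'scan' produced no hits")
  }
  hits <- merge_hits(hits)   # the same region found by several seeds
  hit_seqs <- tibble(
    id = sprintf("hit%04d", seq_len(nrow(hits))),
    residues = map_chr(seq_len(nrow(hits)), function(i) {
      res <- genome$residues[genome$id == hits$seq_id[i]]
      s <- substr0(res, hits$start[i], hits$end[i])
      if (hits$strand[i] == "-") revcomp(s) else s
    })
  )
  clustered <- cluster_hits(hit_seqs, config$cluster_min_coverage,
                            config$cluster_min_identity)
  hits$cluster <- clustered$cluster[match(hit_seqs$id, clustered$id)]
  keep <- as.integer(names(which(table(hits$cluster) >= config$min_cluster_size)))
  families <- list()
  annotations <- list()
  counts <- list()
  solos <- list()
  for (cl in sort(keep)) {
    fid <- sprintf("TRIM-%d", cl)
    cluster <- mutate(filter(hits, .data$cluster == cl), family_id = fid)
    fam <- extend_to_termini(
      cluster, genome, flank = config$flank, max_rounds = config$max_rounds,
      max_members = config$max_members, family_id = fid,
      min_ltr = config$min_ltr, max_ltr = config$max_ltr,
      min_ltr_identity = config$min_ltr_identity
    )
    families[[fid]] <- fam
    if (!fam$complete) next
    annotations[[fid]] <- annotate_family(fam, trna_library, motifs)
    fam$family_class <- annotations[[fid]]$family_class
    families[[fid]] <- fam
    part_hits <- count_family_copies(genome, fam,
                                     min_identity = config$scan_min_identity,
                                     min_length = config$scan_min_length,
                                     seed_k = config$seed_k,
                                     regions = select(cluster, "seq_id", "start", "end"))
    solo <- find_solo_ltrs(part_hits, fam, genome)
    solos[[fid]] <- mutate(solo, family_id = fid)
    counts[[fid]] <- count_full_length(part_hits, fam,
                                       length_frac = config$full_length_frac,
                                       identity_min = config$full_identity,
                                       solo = solo)
  }
  structure(list(families = families, annotations = annotations,
                 counts = bind_rows(counts), solo = bind_rows(solos),
                 hits = hits, clusters = clustered, config = config),
            class = "trim_discovery")
}

#' @export
print.trim_discovery <- function(x, ...) {
  cat(sprintf("<trim_discovery> %d hit(s), %d cluster(s), %d family model(s) (%d complete)\n",
              nrow(x$hits), max(x$clusters$cluster), length(x$families),
              sum(map_lgl(x$families, "complete"))))
  if (length(x$annotations) > 0) print(tidy(x))
  invisible(x)
}

#' @export
#' @method tidy trim_discovery
tidy.trim_discovery <- function(x, ...) {
  if (length(x$annotations) == 0) {
    return(tibble(family_id = character()))
  }
  ann <- bind_rows(map(x$annotations, tidy))
  if (nrow(x$counts) > 0) {
    ann <- left_join(ann, select(x$counts, "family_id", "ltr_full",
                                 "internal_full", "solo_ltr"),
                     by = "family_id")
  }
  ann
}

#' @export
#' @method glance trim_discovery
glance.trim_discovery <- function(x, ...) {
  cls <- map_chr(x$families, "family_class")
  tibble(
    n_hits = nrow(x$hits),
    n_clusters = max(x$clusters$cluster),
    n_families = length(x$families),
    n_complete = sum(map_lgl(x$families, "complete")),
    n_trimp3_trna = sum(cls == "TRIMp3_tRNA"),
    n_trimp3_5s = sum(cls == "TRIMp3_5S"),
    n_trimp2 = sum(cls == "TRIMp2")
  )
}

#' Write discovery outputs to a directory
#'
#' Writes the family library as FASTA (full consensus plus the split `X` /
#' `X-I` convention), a per-family TSV manifest, the hit table, solo calls,
#' copy counts, and a GFF3 of the annotated copies of each complete family.
#'
#' @param x A `trim_discovery`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_discovery <- function(x, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  complete <- keep(x$families, "complete")
  full <- tibble(id = map_chr(complete, "family_id"),
                 residues = map_chr(complete, "consensus"),
                 description = map_chr(complete, "family_class"))
  write_fasta(full, file.path(out_dir, "families.fasta"))
  split_recs <- bind_rows(map(complete, function(f) {
    p <- family_parts(f)
    tibble(id = c(f$family_id, paste0(f$family_id, "-I")),
           residues = c(p$ltr, p$internal),
           description = c("LTR consensus", "internal consensus"))
  }))
  write_fasta(split_recs, file.path(out_dir, "families_split.fasta"))
  readr_write_tsv(tidy(x), file.path(out_dir, "families.tsv"))
  readr_write_tsv(x$hits, file.path(out_dir, "hits.tsv"))
  readr_write_tsv(x$counts, file.path(out_dir, "counts.tsv"))
  readr_write_tsv(x$solo, file.path(out_dir, "solo_ltrs.tsv"))
  feats <- bind_rows(map(complete, function(f) {
    if (is.null(f$copies) || nrow(f$copies) == 0) return(NULL)
    mutate(select(f$copies, "seq_id", "start", "end", "strand"),
           type = "LTR_retrotransposon",
           id = sprintf("%s_copy%d", f$family_id, row_number()))
  }))
  write_gff3(feats %||% tibble(), file.path(out_dir, "copies.gff3"))
  invisible(out_dir)
}

# small TSV writer (avoids a readr dependency for plain tables)
readr_write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' BioNJ tree of family LTR (promoter-carrying) sequences
#'
#' Aligns the 5' LTR consensus of each complete family, computes
#' Jukes-Cantor distances and a BioNJ tree with bootstrap supports. Requires
#' at least four complete families.
#'
#' @param families List of partitioned [trim_family] objects.
#' @param n Bootstrap replicates.
#' @param seed Bootstrap seed.
#' @return A `phylo` with support values in `node.label`.
#' @export
family_ltr_tree <- function(families, n = 100, seed = 1) {
  families <- keep(families, "complete")
  if (length(families) < 4) abort("family_ltr_tree requires at least 4 complete families")
  ltrs <- tibble(id = map_chr(families, "family_id"),
                 residues = map_chr(families, ~ family_parts(.x)$ltr))
  msa <- build_msa(ltrs)
  bootstrap_support(msa, n = n, seed = seed)
}
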