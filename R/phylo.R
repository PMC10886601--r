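# Jukes-Cantor distances, BioNJ trees and column-bootstrap supports for
# promoter / tRNA-like sequence alignments.

#' Jukes-Cantor distance between two aligned rows
#'
#' Pairwise deletion: only columns where both rows carry a base (non-gap) are
#' compared. With mismatch proportion `p` over those columns, the distance is
#' `d = -(3/4) ln(1 - 4p/3)`. For `p >= 0.75` the formula is undefined
#' (saturation); the distance is capped at `max_distance` and flagged with
#' attribute `saturated = TRUE`.
#'
#' @param row_a,row_b Equal-length gapped aligned strings.
#' @param max_distance Cap applied at saturation (substitutions/site).
#' @return The distance (substitutions/site), with attributes `p` and
#'   `saturated`.
#' @export
jc_distance <- function(row_a, row_b, max_distance = 5) {
  stopifnot(nchar(row_a) == nchar(row_b))
  a <- chars(toupper(row_a)); b <- chars(toupper(row_b))
  shared <- a != "-" & b != "-"
  if (!any(shared)) abort("no shared non-gap columns between rows")
  p <- mean(a[shared] != b[shared])
  if (p >= 0.75) {
    return(structure(max_distance, p = p, saturated = TRUE))
  }
  structure(-0.75 * log(1 - 4 * p / 3), p = p, saturated = FALSE)
}

#' Jukes-Cantor distance matrix of a multiple alignment
#'
#' @param msa A `trim_msa` tibble (columns `id`, `aligned`).
#' @param max_distance Saturation cap, see [jc_distance()].
#' @return A `dist` object over the alignment rows, with a matching matrix of
#'   raw mismatch proportions in attribute `p_raw`.
#' @export
jc_distance_matrix <- function(msa, max_distance = 5) {
  n <- nrow(msa)
  d <- matrix(0, n, n, dimnames = list(msa$id, msa$id))
  p <- matrix(0, n, n, dimnames = list(msa$id, msa$id))
  if (n > 1) {
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        dij <- jc_distance(msa$aligned[i], msa$aligned[j], max_distance)
        d[i, j] <- d[j, i] <- as.numeric(dij)
        p[i, j] <- p[j, i] <- attr(dij, "p")
      }
    }
  }
  structure(as.dist(d), p_raw = p)
}

#' BioNJ tree from a distance matrix
#'
#' Agglomerative neighbor joining with BioNJ's variance-weighted distance
#' reduction. Negative branch lengths are clamped to zero.
#'
#' @param dm A `dist` object or symmetric matrix over at least 3 taxa.
#' @return An unrooted `phylo` tree.
#' @export
bionj_tree <- function(dm) {
  if (!inherits(dm, "dist")) dm <- as.dist(as.matrix(dm))
  n <- attr(dm, "Size")
  if (n < 3) abort("bionj_tree requires at least 3 taxa")
  tree <- ape::bionj(dm)
  tree$edge.length <- pmax(tree$edge.length, 0)
  tree
}

#' Bootstrap supports for a reference tree
#'
#' Resamples alignment columns with replacement `n` times (seeded), rebuilds
#' a tree per replicate with `tree_builder`, and reports for each internal
#' bipartition of the reference tree the percentage of replicates containing
#' it, stored in `node.label`.
#'
#' @param msa A `trim_msa` tibble with at least 4 rows.
#' @param tree_builder Function mapping an msa to a `phylo` (default:
#'   Jukes-Cantor + BioNJ).
#' @param n Number of bootstrap replicates.
#' @param seed Random seed for the column resampling.
#' @return The reference `phylo` with internal-node support values (0-100) in
#'   `node.label`.
#' @export
bootstrap_support <- function(msa, tree_builder = NULL, n = 100, seed = 1) {
  stopifnot(nrow(msa) >= 4)
  if (is.null(tree_builder)) {
    tree_builder <- function(m) bionj_tree(jc_distance_matrix(m))
  }
  mat <- do.call(rbind, strsplit(msa$aligned, "", fixed = TRUE))
  ref <- tree_builder(msa)
  boot <- vector("list", n)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  ncol_full <- ncol(mat)
  for (b in seq_len(n)) {
    cols <- sample.int(ncol_full, ncol_full, replace = TRUE)
    bm <- mat[, cols, drop = FALSE]
    bmsa <- tibble(id = msa$id, aligned = apply(bm, 1, paste, collapse = ""))
    boot[[b]] <- tree_builder(bmsa)
  }
  counts <- ape::prop.clades(ref, boot, rooted = FALSE)
  counts[is.na(counts)] <- 0
  ref$node.label <- round(100 * counts / n, 1)
  ref
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
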