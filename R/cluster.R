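#' Pearson-distance matrix between interaction profiles
#'
#' Distance between two genes' interaction profiles is 1 minus the Pearson
#' correlation of their score-matrix rows. The cells coupling the two
#' genes to themselves and to each other are excluded from the correlated
#' vectors (self-scores are controls, not profile signal); for consensus
#' matrices the exclusion is applied within every condition block.
#' Unmeasured cells are imputed as 0 — the null-interaction value on the
#' z scale — for clustering only. Rows with zero variance are dropped with
#' a warning.
#'
#' @param m a `gi_map`, a plain numeric matrix of profiles (rows =
#'   genes), or a `gi_consensus`.
#' @param blocks number of horizontally concatenated condition blocks
#'   (inferred for `gi_consensus` input).
#' @return a [stats::dist] object (Pearson distance, in `[0, 2]`).
#' @export
correlation_distance <- function(m, blocks = 1L) {
  if (inherits(m, "gi_consensus")) {
    blocks <- length(m$conditions)
    X <- m$matrix
  } else if (inherits(m, "gi_map")) {
    X <- m$scores
  } else {
    X <- as.matrix(m)
  }
  if (nrow(X) < 3L) stop("need at least 3 profiles to compute distances")
  X[!is.finite(X)] <- 0
  keep <- apply(X, 1L, stats::sd) > 0
  if (!all(keep)) {
    warning(sum(!keep), " zero-variance profile(s) excluded: ",
            paste(rownames(X)[!keep], collapse = ", "))
    X <- X[keep, , drop = FALSE]
  }
  d <- profile_distance(X, blocks)
  stats::as.dist(d)
}

## Pairwise 1 - cor with per-pair exclusion of the self/partner columns in
## every block. X is n x (n_block * blocks) where columns within a block
## follow the row ordering.
profile_distance <- function(X, blocks = 1L) {
  n <- nrow(X)
  nb <- ncol(X) / blocks
  if (nb != round(nb))
    stop("column count is not a multiple of the block count")
  offsets <- (seq_len(blocks) - 1L) * nb
  D <- matrix(0, n, n, dimnames = list(rownames(X), rownames(X)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ex <- as.vector(outer(c(i, j), offsets, "+"))
      D[i, j] <- D[j, i] <- 1 - stats::cor(X[i, -ex], X[j, -ex])
    }
  }
  D
}

#' Average-linkage hierarchical clustering of interaction profiles
#'
#' Agglomerates a Pearson-distance matrix with average linkage
#' (UPGMA). The merge heights are average Pearson distances, so flat
#' clusters cut at distance 0.55 correspond to tight, complex-like
#' modules and cuts at 0.8 to broader functional systems.
#'
#' @param d a [stats::dist] from [correlation_distance()], or anything
#'   [stats::as.dist()] accepts.
#' @return A `gi_clustering`: list with the [stats::hclust] tree and the
#'   leaf labels.
#' @export
hierarchical_cluster <- function(d) {
  h <- stats::hclust(stats::as.dist(d), method = "average")
  structure(list(hclust = h, labels = h$labels), class = "gi_clustering")
}

#' @export
print.gi_clustering <- function(x, ...) {
  cat(sprintf("Average-linkage clustering of %d profiles (max merge height %.3f)\n",
              length(x$labels), max(x$hclust$height)))
  invisible(x)
}

#' @export
plot.gi_clustering <- function(x, ...) {
  plot(x$hclust, hang = -1, xlab = "", sub = "",
       ylab = "Pearson distance", ...)
  invisible(x)
}

#' Flat clusters at a distance threshold
#'
#' Cuts the tree so that genes whose merge height is at most `threshold`
#' share a cluster; singletons are allowed. Cuts at a smaller threshold
#' always refine cuts at a larger one.
#'
#' @param model a `gi_clustering`.
#' @param threshold Pearson-distance cut height (e.g. 0.55 for
#'   complex-level modules, 0.8 for systems).
#' @return named integer vector of cluster assignments.
#' @export
cut_clusters <- function(model, threshold) {
  stop_if_not_class(model, "gi_clustering", "model")
  stats::cutree(model$hclust, h = threshold)
}

#' Consensus interaction matrix and clustering across conditions
#'
#' Normalizes each gene-level map by its own global score standard
#' deviation, imputes unmeasured cells as 0, concatenates the maps along
#' the column axis into an `n x (n * k)` composite, and clusters the rows
#' with average-linkage Pearson distance ([correlation_distance()] with
#' per-block self-exclusion). The resulting dendrogram is a universal
#' ordering that can be applied back to each individual map.
#'
#' @param maps list of two or more gene-level `gi_map` objects (or plain
#'   matrices) over the same gene universe.
#' @return A `gi_consensus`: list with `matrix` (the composite),
#'   `conditions` (block labels, in input order), and `model`
#'   (a `gi_clustering` of the rows).
#' @export
consensus_cluster <- function(maps) {
  if (length(maps) < 2L) stop("need at least 2 maps for a consensus")
  mats <- lapply(maps, function(m) if (inherits(m, "gi_map")) m$scores else as.matrix(m))
  genes <- rownames(mats[[1L]])
  for (m in mats) {
    if (!identical(sort(rownames(m)), sort(genes)))
      stop("all maps must share the same gene universe")
  }
  conds <- names(maps) %||% as.character(seq_along(maps))
  if (is.null(names(maps)) && inherits(maps[[1L]], "gi_map"))
    conds <- vapply(maps, function(m) m$condition, character(1L))
  norm <- lapply(mats, function(m) {
    m <- m[genes, genes]
    s <- stats::sd(m[is.finite(m)])
    m <- m / s
    m[!is.finite(m)] <- 0
    m
  })
  comp <- do.call(cbind, norm)
  colnames(comp) <- paste(rep(conds, each = length(genes)),
                          rep(genes, length(norm)), sep = ".")
  obj <- structure(list(matrix = comp, conditions = conds), class = "gi_consensus")
  obj$model <- hierarchical_cluster(correlation_distance(obj))
  obj
}

#' @export
print.gi_consensus <- function(x, ...) {
  cat(sprintf("Consensus matrix: %d genes x %d columns (%d conditions: %s)\n",
              nrow(x$matrix), ncol(x$matrix), length(x$conditions),
              paste(x$conditions, collapse = ", ")))
  invisible(x)
}

#' Same-gene vs. different-gene sgRNA profile correlation
#'
#' Clustering-fidelity metric: the Pearson correlation between the
#' interaction profiles of the two sgRNAs targeting the same gene should
#' exceed that of sgRNAs targeting different genes. Profiles are rows of
#' an sgRNA-level score matrix (ntc rows excluded); the self/partner cells
#' are excluded pairwise as in [correlation_distance()].
#'
#' @param sg an sgRNA-level `gi_map`, or a numeric profile matrix with
#'   rownames.
#' @param gene_map named character vector `sgrna_id -> gene` (taken from
#'   the map when available).
#' @param blocks number of concatenated condition blocks in the profile
#'   matrix.
#' @param max_different cap on the number of different-gene pairs
#'   evaluated; an evenly spaced subset is used beyond it.
#' @return list with `same`, `different` (correlation vectors),
#'   `median_same`, `median_different`.
#' @export
sgrna_fidelity <- function(sg, gene_map = NULL, blocks = 1L,
                           max_different = 20000L) {
  if (inherits(sg, "gi_map")) {
    gene_map <- gene_map %||% sg$gene_map
    X <- sg$scores
  } else {
    X <- as.matrix(sg)
  }
  if (is.null(gene_map)) stop("'gene_map' is required")
  X[!is.finite(X)] <- 0
  nb <- ncol(X) / blocks
  ## within a block, column k is the partner column of row k of the full
  ## matrix; remember original row positions before dropping ntc rows
  orig <- seq_len(nrow(X))
  keep <- rownames(X) %in% names(gene_map)[gene_map != "ntc"]
  orig <- orig[keep]
  X <- X[keep, , drop = FALSE]
  genes <- gene_map[rownames(X)]
  n <- nrow(X)
  offsets <- (seq_len(blocks) - 1L) * nb
  pair_cor <- function(i, j) {
    ex <- as.vector(outer(c(orig[i], orig[j]), offsets, "+"))
    stats::cor(X[i, -ex], X[j, -ex])
  }
  pairs <- utils::combn(n, 2L)
  same_idx <- genes[pairs[1L, ]] == genes[pairs[2L, ]]
  same <- vapply(which(same_idx), function(k)
    pair_cor(pairs[1L, k], pairs[2L, k]), numeric(1L))
  diff_ks <- which(!same_idx)
  if (length(diff_ks) > max_different)
    diff_ks <- diff_ks[round(seq(1L, length(diff_ks),
                                 length.out = max_different))]
  different <- vapply(diff_ks, function(k)
    pair_cor(pairs[1L, k], pairs[2L, k]), numeric(1L))
  list(same = same, different = different,
       median_same = stats::median(same, na.rm = TRUE),
       median_different = stats::median(different, na.rm = TRUE))
}

#' Write cluster assignments and the linkage table as TSV
#'
#' Assignments as `gene  cluster_id  threshold`; the linkage as the
#' standard row-per-merge table (`merge1, merge2, height`).
#'
#' @param model a `gi_clustering`.
#' @param thresholds numeric vector of cut heights.
#' @param path file path for the assignments.
#' @param linkage_path optional path for the merge table.
#' @export
write_clusters <- function(model, thresholds, path, linkage_path = NULL) {
  stop_if_not_class(model, "gi_clustering", "model")
  out <- do.call(rbind, lapply(thresholds, function(t) {
    cl <- cut_clusters(model, t)
    data.frame(gene = names(cl), cluster_id = unname(cl), threshold = t,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(linkage_path)) {
    h <- model$hclust
    utils::write.table(
      data.frame(merge1 = h$merge[, 1L], merge2 = h$merge[, 2L],
                 height = h$height),
      linkage_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
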