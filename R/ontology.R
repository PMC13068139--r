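#' Compress a gene-level map to an ontology-level matrix
#'
#' Averages a gene-level interaction matrix within and between gene
#' clusters: cell (C1, C2) is the mean score over all gene pairs with one
#' gene in each cluster; the diagonal is the mean intra-cluster pairwise
#' score over distinct gene pairs (a singleton cluster keeps its gene's
#' own diagonal score, so compressing with all-singleton clusters is the
#' identity). Masked gene pairs are omitted from the means.
#'
#' @param m a gene-level `gi_map` or a symmetric numeric matrix.
#' @param clusters named vector `gene -> cluster id` (e.g. from
#'   [cut_clusters()]); every gene of the matrix must be assigned.
#' @return An `ontology_matrix`: the clusters x clusters matrix, with the
#'   cluster membership in `attr(, "membership")`.
#' @export
compress_to_ontology <- function(m, clusters) {
  sc <- if (inherits(m, "gi_map")) m$scores else as.matrix(m)
  genes <- rownames(sc)
  if (!all(genes %in% names(clusters)))
    stop("every gene in the matrix must have a cluster assignment")
  cl <- clusters[genes]
  ids <- sort(unique(unname(cl)))
  members <- split(genes, cl)
  if (any(lengths(members) == 0L)) stop("empty cluster")
  K <- length(ids)
  out <- matrix(NA_real_, K, K, dimnames = list(ids, ids))
  for (i in seq_len(K)) {
    gi_ <- members[[as.character(ids[i])]]
    for (j in i:K) {
      gj <- members[[as.character(ids[j])]]
      sub <- sc[gi_, gj, drop = FALSE]
      vals <- if (i == j) {
        if (length(gi_) == 1L) sub[1L, 1L] else sub[upper.tri(sub)]
      } else {
        as.numeric(sub)
      }
      vals <- vals[is.finite(vals)]
      if (length(vals)) out[i, j] <- out[j, i] <- mean(vals)
    }
  }
  structure(out, membership = members, class = c("ontology_matrix", "matrix"))
}

#' Differential ontology matrix and gained/lost edges
#'
#' Elementwise difference of two ontology-level matrices over the same
#' cluster set, with cluster-pair edges labelled *gained* (magnitude above
#' `threshold` in the environmental matrix but not the reference) or
#' *lost* (the converse).
#'
#' @param env,ref `ontology_matrix` objects with identical cluster sets.
#' @param threshold magnitude defining a present edge.
#' @return list with `diff` (the difference matrix, env minus ref) and
#'   `edges` (data frame `cluster_a, cluster_b, env, ref, diff, status`
#'   restricted to gained/lost edges).
#' @export
ontology_differential <- function(env, ref, threshold) {
  if (!identical(dimnames(env), dimnames(ref)))
    stop("the two ontology matrices must have identical cluster sets")
  d <- unclass(env) - unclass(ref)
  ut <- which(upper.tri(d, diag = TRUE), arr.ind = TRUE)
  e <- unclass(env)[ut]
  r <- unclass(ref)[ut]
  status <- rep(NA_character_, length(e))
  status[abs(e) > threshold & abs(r) <= threshold] <- "gained"
  status[abs(r) > threshold & abs(e) <= threshold] <- "lost"
  keep <- !is.na(status)
  edges <- data.frame(
    cluster_a = rownames(d)[ut[keep, 1L]],
    cluster_b = colnames(d)[ut[keep, 2L]],
    env = e[keep], ref = r[keep], diff = (e - r)[keep],
    status = status[keep],
    stringsAsFactors = FALSE
  )
  list(diff = d, edges = edges)
}

#' Cross-condition coordination profile of a query ontology
#'
#' For each condition, correlates the query cluster's ontology-level
#' interaction profile with every other cluster's profile (the cells
#' coupling the two clusters to themselves and each other are excluded),
#' tracking which ontologies a module coordinates with — and how that
#' coordination rewires — across environments.
#'
#' @param query cluster id present in every matrix.
#' @param maps named list of `ontology_matrix` objects (one per
#'   condition) over the same cluster set.
#' @return data frame `(condition, cluster, r)` sorted within condition
#'   by decreasing correlation.
#' @export
coordination_profile <- function(query, maps) {
  if (is.null(names(maps))) names(maps) <- as.character(seq_along(maps))
  out <- lapply(names(maps), function(cond) {
    m <- unclass(maps[[cond]])
    if (!as.character(query) %in% rownames(m))
      stop("query cluster '", query, "' absent from condition '", cond, "'")
    qi <- match(as.character(query), rownames(m))
    others <- setdiff(seq_len(nrow(m)), qi)
    r <- vapply(others, function(j) {
      ex <- c(qi, j)
      stats::cor(m[qi, -ex], m[j, -ex], use = "complete.obs")
    }, numeric(1L))
    df <- data.frame(condition = cond, cluster = rownames(m)[others], r = r,
                     stringsAsFactors = FALSE)
    df[order(-df$r), ]
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write an ontology matrix as TSV
#'
#' @param m an `ontology_matrix`.
#' @param path file path.
#' @export
write_ontology_matrix <- function(m, path) {
  df <- data.frame(cluster = rownames(m), unclass(m), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
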