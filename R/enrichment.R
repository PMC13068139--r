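#' Enrichment of interaction strength for known protein-protein interactions
#'
#' Bins every unique measured gene pair of a gene-level map by the
#' magnitude of its interaction score and asks whether strong interactions
#' are enriched for known physical interactions. Each bin's mean PPI score
#' (a pair absent from the table scores 0 — no interaction detected) is
#' normalized by the mean PPI score over all unique pairs in the map,
#' giving an enrichment over background per bin. A chi-square test over
#' the same bins uses categorical interacting / not-interacting counts,
#' with expected counts from the global interacting fraction; bins with
#' expected counts below 5 are merged with their neighbour.
#'
#' @param m a gene-level `gi_map` or symmetric matrix.
#' @param ppi data frame `(gene_a, gene_b, escore)` with scores in
#'   `[0, 1]`; unordered pairs, absent pairs count as 0.
#' @param n_bins number of bins (default 10).
#' @param method `"quantile"` (default, equal-occupancy) or `"width"`
#'   (equal-width) binning of the absolute score.
#' @return list with `bins` (data frame `bin, n, mean_abs_score,
#'   mean_escore, enrichment`), `chisq_p`, `chisq_stat`, and
#'   `background` (the global mean escore).
#' @export
ppi_enrichment <- function(m, ppi, n_bins = 10L, method = c("quantile", "width")) {
  method <- match.arg(method)
  sc <- if (inherits(m, "gi_map")) m$scores else as.matrix(m)
  ut <- which(upper.tri(sc), arr.ind = TRUE)
  pairs <- data.frame(
    gene_a = rownames(sc)[ut[, 1L]],
    gene_b = colnames(sc)[ut[, 2L]],
    score = sc[ut], stringsAsFactors = FALSE
  )
  pairs <- pairs[is.finite(pairs$score), , drop = FALSE]
  esc <- stats::setNames(ppi$escore, pair_key(ppi$gene_a, ppi$gene_b))
  if (anyDuplicated(names(esc))) stop("duplicate pairs in the PPI table")
  hit <- esc[pair_key(pairs$gene_a, pairs$gene_b)]
  pairs$escore <- ifelse(is.na(hit), 0, hit)
  if (all(pairs$escore == 0))
    stop("no PPI scores overlap the map universe: enrichment undefined")

  a <- abs(pairs$score)
  breaks <- if (method == "quantile") {
    unique(stats::quantile(a, probs = seq(0, 1, length.out = n_bins + 1L)))
  } else {
    seq(min(a), max(a), length.out = n_bins + 1L)
  }
  pairs$bin <- cut(a, breaks, include.lowest = TRUE, labels = FALSE)
  background <- mean(pairs$escore)

  bins <- do.call(rbind, lapply(sort(unique(pairs$bin)), function(b) {
    p <- pairs[pairs$bin == b, ]
    data.frame(bin = b, n = nrow(p), mean_abs_score = mean(abs(p$score)),
               mean_escore = mean(p$escore),
               enrichment = mean(p$escore) / background,
               n_interacting = sum(p$escore > 0))
  }))

  ## chi-square on interacting counts, expected from the global fraction
  frac <- sum(pairs$escore > 0) / nrow(pairs)
  obs_i <- bins$n_interacting
  obs_n <- bins$n - bins$n_interacting
  exp_i <- bins$n * frac
  exp_n <- bins$n * (1 - frac)
  ## merge adjacent bins until all expected counts are >= 5
  while (length(obs_i) > 1L && any(pmin(exp_i, exp_n) < 5)) {
    k <- which.min(pmin(exp_i, exp_n))
    into <- if (k == 1L) 2L else k - 1L
    obs_i[into] <- obs_i[into] + obs_i[k]
    obs_n[into] <- obs_n[into] + obs_n[k]
    exp_i[into] <- exp_i[into] + exp_i[k]
    exp_n[into] <- exp_n[into] + exp_n[k]
    obs_i <- obs_i[-k]; obs_n <- obs_n[-k]
    exp_i <- exp_i[-k]; exp_n <- exp_n[-k]
  }
  cells_o <- c(obs_i, obs_n)
  cells_e <- c(exp_i, exp_n)
  ok <- cells_e > 0
  stat <- sum((cells_o[ok] - cells_e[ok])^2 / cells_e[ok])
  df <- max(length(obs_i) - 1L, 1L)
  p <- stats::pchisq(stat, df = df, lower.tail = FALSE)

  list(bins = bins, chisq_stat = stat, chisq_df = df, chisq_p = p,
       background = background)
}

#' Read a gene-set collection in GMT format
#'
#' Thin wrapper around [fgsea::gmtPathways()].
#'
#' @param path path to a `.gmt` file.
#' @return named list of character vectors (term -> member genes).
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Iterative gene-set enrichment with top-term removal
#'
#' Hypergeometric over-representation of every gene set against the
#' current hit list, with Benjamini-Hochberg adjustment across sets; the
#' most enriched term is recorded, its member genes are removed from the
#' hit list, and the procedure repeats — yielding the top `n_iter`
#' mutually exclusive, non-overlapping terms. Terms whose
#' `-log10(adjusted p)` falls below `min_neglogp` are reported but
#' flagged non-significant. Stops early when the hit list empties.
#'
#' @param hits character vector of hit genes (must lie in the universe).
#' @param gene_sets named list of character vectors ([read_gmt()]).
#' @param universe background gene universe; defaults to the union of all
#'   set members and the hits.
#' @param n_iter maximum number of iterations (default 10).
#' @param min_neglogp significance threshold on `-log10(adjusted p)`
#'   (default 6).
#' @return data frame, one row per iteration: `(iteration, term, p_value,
#'   p_adjusted, n_overlap, n_set, n_hits_remaining, significant,
#'   genes_removed)` where `genes_removed` is a comma-separated list.
#' @export
iterative_enrichment <- function(hits, gene_sets, universe = NULL,
                                 n_iter = 10L, min_neglogp = 6) {
  universe <- universe %||% unique(c(unlist(gene_sets, use.names = FALSE), hits))
  if (!all(hits %in% universe)) stop("all hits must lie in the universe")
  gene_sets <- lapply(gene_sets, function(s) intersect(unique(s), universe))
  current <- unique(hits)
  N <- length(universe)
  out <- list()

  for (it in seq_len(n_iter)) {
    if (!length(current)) break
    n <- length(current)
    stats_tab <- vapply(gene_sets, function(s) {
      K <- length(s)
      k <- length(intersect(s, current))
      p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
      c(k = k, K = K, p = p)
    }, numeric(3L))
    p_adj <- stats::p.adjust(stats_tab["p", ], method = "BH")
    best <- which.min(p_adj)
    if (length(best) > 1L) best <- best[1L]
    ## break exact ties on raw p, then name order (vapply order is stable)
    ties <- which(p_adj == p_adj[best])
    if (length(ties) > 1L) best <- ties[which.min(stats_tab["p", ties])]
    term <- names(gene_sets)[best]
    removed <- intersect(gene_sets[[best]], current)
    out[[it]] <- data.frame(
      iteration = it, term = term,
      p_value = stats_tab["p", best], p_adjusted = p_adj[best],
      n_overlap = as.integer(stats_tab["k", best]),
      n_set = as.integer(stats_tab["K", best]),
      n_hits_remaining = n,
      significant = -log10(p_adj[best]) >= min_neglogp,
      genes_removed = paste(removed, collapse = ","),
      stringsAsFactors = FALSE
    )
    current <- setdiff(current, removed)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Read a PPI score table
#'
#' TSV with columns `gene_a`, `gene_b`, `escore` (scores in `[0, 1]`).
#'
#' @param path file path.
#' @return data frame with canonicalized unordered pairs.
#' @export
read_ppi <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  names(df)[1:3] <- c("gene_a", "gene_b", "escore")
  a <- pmin(df$gene_a, df$gene_b)
  b <- pmax(df$gene_a, df$gene_b)
  df$gene_a <- a
  df$gene_b <- b
  if (anyDuplicated(pair_key(a, b))) stop("duplicate pairs in PPI table")
  df
}
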