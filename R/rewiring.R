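#' Differential genetic-interaction (dGI) matrix
#'
#' Subtracts a reference interaction map from an environmental map,
#' elementwise per gene pair, over the genes common to both maps. A pair
#' masked (unmeasured) in either map is masked in the difference — never
#' silently zeroed. The control dGI distribution is the matched difference
#' of gene-ntc control scores, used by [call_high_confidence_dgi()] to set
#' the significance threshold.
#'
#' @param egi gene-level `gi_map` for the environmental condition.
#' @param gi gene-level `gi_map` for the reference condition.
#' @return A `dgi_map`: list with `scores` (symmetric difference matrix),
#'   `control_scores`, `env_condition`, `ref_condition`.
#' @export
compute_dgi <- function(egi, gi) {
  stop_if_not_class(egi, "gi_map", "egi")
  stop_if_not_class(gi, "gi_map", "gi")
  if (egi$level != "gene" || gi$level != "gene")
    stop("both maps must be gene-level")
  common <- intersect(rownames(egi$scores), rownames(gi$scores))
  if (!length(common)) stop("the two maps share no genes")
  d <- egi$scores[common, common] - gi$scores[common, common]
  ctrl_names <- intersect(names(egi$control_scores), names(gi$control_scores))
  ctrl <- egi$control_scores[ctrl_names] - gi$control_scores[ctrl_names]
  structure(list(scores = d, control_scores = ctrl,
                 env_condition = egi$condition,
                 ref_condition = gi$condition),
            class = "dgi_map")
}

#' @export
print.dgi_map <- function(x, ...) {
  cat(sprintf("Differential GI map: '%s' - '%s'\n",
              x$env_condition, x$ref_condition))
  cat(sprintf("  %d genes, %d measured pairs, %d control dGIs (sd %.3f)\n",
              nrow(x$scores),
              sum(is.finite(x$scores[upper.tri(x$scores)])),
              length(x$control_scores), stats::sd(x$control_scores)))
  invisible(x)
}

#' Call high-confidence differential interactions
#'
#' A dGI is significant when (i) its magnitude strictly exceeds `n_sd`
#' standard deviations of the control dGI distribution and (ii) the pair
#' reached significance in at least one of the two original maps — dGIs
#' where neither original score is significant are excluded, however large
#' the difference.
#'
#' @param d a [compute_dgi()] result.
#' @param egi_calls,gi_calls calls tables from [call_high_confidence()]
#'   for the environmental and reference maps (at their own thresholds,
#'   conventionally 4 SD).
#' @param n_sd threshold in control-dGI standard deviations (default 5).
#' @return data frame `(gene_a, gene_b, dgi, sign, exceeds_threshold,
#'   supported_by_original, significant)`; threshold in
#'   `attr(, "threshold")`.
#' @export
call_high_confidence_dgi <- function(d, egi_calls, gi_calls, n_sd = 5) {
  stop_if_not_class(d, "dgi_map", "d")
  if (!length(d$control_scores)) stop("dGI map has no control scores")
  thr <- n_sd * stats::sd(d$control_scores)
  sc <- d$scores
  ut <- which(upper.tri(sc), arr.ind = TRUE)
  calls <- data.frame(
    gene_a = rownames(sc)[ut[, 1L]],
    gene_b = colnames(sc)[ut[, 2L]],
    dgi = sc[ut],
    stringsAsFactors = FALSE
  )
  calls <- calls[is.finite(calls$dgi), , drop = FALSE]
  key <- pair_key(calls$gene_a, calls$gene_b)
  sig_in <- function(cl) {
    k <- pair_key(cl$gene_a, cl$gene_b)[cl$significant]
    key %in% k
  }
  calls$sign <- ifelse(calls$dgi > 0, "gained_positive", "gained_negative")
  calls$exceeds_threshold <- abs(calls$dgi) > thr
  calls$supported_by_original <- sig_in(egi_calls) | sig_in(gi_calls)
  calls$significant <- calls$exceeds_threshold & calls$supported_by_original
  attr(calls, "threshold") <- thr
  calls
}

#' Robustness of dGIs to the choice of reference map
#'
#' Compares two dGI matrices for the same environmental condition computed
#' against different (matched vs. unmatched) reference maps: Pearson
#' correlation of the two score vectors over all commonly measured pairs,
#' and over the union of pairs whose dGI magnitude exceeds `n_sd` control
#' standard deviations in either matrix.
#'
#' @param dgi_matched,dgi_unmatched two `dgi_map` objects over the same
#'   gene universe.
#' @param n_sd threshold defining the significant-pair subset (default 5).
#' @return list with `r_all`, `r_significant`, `n_all`, `n_significant`.
#' @export
unmatched_reference_check <- function(dgi_matched, dgi_unmatched, n_sd = 5) {
  stop_if_not_class(dgi_matched, "dgi_map", "dgi_matched")
  stop_if_not_class(dgi_unmatched, "dgi_map", "dgi_unmatched")
  common <- intersect(rownames(dgi_matched$scores),
                      rownames(dgi_unmatched$scores))
  m1 <- dgi_matched$scores[common, common]
  m2 <- dgi_unmatched$scores[common, common]
  ut <- upper.tri(m1)
  v1 <- m1[ut]
  v2 <- m2[ut]
  ok <- is.finite(v1) & is.finite(v2)
  thr1 <- n_sd * stats::sd(dgi_matched$control_scores)
  thr2 <- n_sd * stats::sd(dgi_unmatched$control_scores)
  sig <- ok & (abs(v1) > thr1 | abs(v2) > thr2)
  list(
    r_all = stats::cor(v1[ok], v2[ok]),
    r_significant = if (sum(sig) >= 3L) stats::cor(v1[sig], v2[sig]) else NA_real_,
    n_all = sum(ok), n_significant = sum(sig)
  )
}

#' Write a combined GI/eGI/dGI table as TSV
#'
#' Long format `(gene_a, gene_b, gi, egi, dgi, gi_sig, egi_sig, dgi_sig)`.
#'
#' @param d a `dgi_map`.
#' @param egi,gi the two source maps.
#' @param path file path.
#' @param n_sd_gi,n_sd_dgi thresholds for the significance columns.
#' @export
write_dgi_table <- function(d, egi, gi, path, n_sd_gi = 4, n_sd_dgi = 5) {
  egi_calls <- call_high_confidence(egi, n_sd_gi)
  gi_calls <- call_high_confidence(gi, n_sd_gi)
  dcalls <- call_high_confidence_dgi(d, egi_calls, gi_calls, n_sd_dgi)
  key <- pair_key(dcalls$gene_a, dcalls$gene_b)
  gkey <- pair_key(gi_calls$gene_a, gi_calls$gene_b)
  ekey <- pair_key(egi_calls$gene_a, egi_calls$gene_b)
  out <- data.frame(
    gene_a = dcalls$gene_a, gene_b = dcalls$gene_b,
    gi = gi_calls$score[match(key, gkey)],
    egi = egi_calls$score[match(key, ekey)],
    dgi = dcalls$dgi,
    gi_sig = gi_calls$significant[match(key, gkey)],
    egi_sig = egi_calls$significant[match(key, ekey)],
    dgi_sig = dcalls$significant,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
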