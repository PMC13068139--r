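#' Fit the per-query interaction expectation model
#'
#' For one query sgRNA, models the phenotype of every construct containing
#' the query as a quadratic function of the partner sgRNA's single
#' phenotype (ordinary least squares). The residual of a construct from
#' this model is the raw interaction signal for that sgRNA pair. With
#' fewer than `min_quadratic` partners the fit falls back to a straight
#' line; fewer than 3 partners is an error.
#'
#' @param partner_singles numeric vector of partner single phenotypes.
#' @param pair_phenotypes numeric vector of matching construct phenotypes.
#' @param min_quadratic minimum number of points for the quadratic term
#'   (default 5).
#' @return list with `coefficients` (intercept, linear, quadratic),
#'   `fitted`, `residuals`, `degree`.
#' @examples
#' x <- seq(-0.5, 0.5, length.out = 11)
#' fit <- fit_query_model(x, 0.2 + x)       # additive data
#' max(abs(fit$residuals))                  # ~0
#' @export
fit_query_model <- function(partner_singles, pair_phenotypes,
                            min_quadratic = 5L) {
  ok <- is.finite(partner_singles) & is.finite(pair_phenotypes)
  x <- partner_singles[ok]
  y <- pair_phenotypes[ok]
  if (length(x) < 3L)
    stop("need at least 3 partner measurements to fit a query model")
  degree <- if (length(x) >= min_quadratic) 2L else 1L
  X <- if (degree == 2L) cbind(1, x, x^2) else cbind(1, x)
  fit <- stats::lm.fit(X, y)
  cf <- c(fit$coefficients, 0)[1:3]
  names(cf) <- c("intercept", "linear", "quadratic")
  res <- rep(NA_real_, length(ok))
  fitted <- rep(NA_real_, length(ok))
  res[ok] <- fit$residuals
  fitted[ok] <- y - fit$residuals
  list(coefficients = cf, fitted = fitted, residuals = res, degree = degree)
}

#' Score sgRNA-level genetic interactions
#'
#' The central scoring step. For each query sgRNA and replicate, the
#' phenotypes of all constructs containing the query (both cassette
#' orientations) are regressed on the partner sgRNAs' single phenotypes
#' ([fit_query_model()]). Each construct's residual is z-normalized by the
#' standard deviation of the query's residuals over its ntc-paired
#' constructs — the query-specific null spread. Scores for an unordered
#' sgRNA pair are then averaged over both orientations and both query
#' roles (up to four values per replicate), and replicate-level pair
#' scores are averaged last. Negative scores are synthetic-sick
#' (combination more deleterious than the model expectation); positive
#' scores are buffering.
#'
#' Queries that are filtered in the condition, have fewer than 3 usable
#' partners, or lack at least `min_null` ntc residuals are excluded (with
#' a message).
#'
#' @param cp a [compute_construct_phenotypes()] result.
#' @param singles a [single_sgrna_phenotypes()] result.
#' @param library the `gi_library`.
#' @param condition condition to score; the phenotype channel is gamma
#'   when `condition` is the reference, tau otherwise.
#' @param min_quadratic see [fit_query_model()].
#' @param min_null minimum ntc residuals for the null spread (default 2).
#' @return A `gi_map` object at sgRNA level: list with `scores` (symmetric
#'   sgRNA x sgRNA matrix over scored sgRNAs, targeting and ntc), `n_obs`
#'   (contributing measurements), `control_scores` (sgRNA-ntc and ntc-ntc
#'   pair scores), `level = "sgrna"`, `condition`, `channel`.
#' @export
score_sgrna_gis <- function(cp, singles, library, condition,
                            min_quadratic = 5L, min_null = 2L) {
  stop_if_not_class(cp, "construct_phenotypes", "cp")
  stop_if_not_class(library, "gi_library", "library")
  ph <- cp$phenotypes
  ph <- ph[ph$condition == condition & !ph$filtered, , drop = FALSE]
  if (!nrow(ph)) stop("no unfiltered phenotypes for condition '", condition, "'")
  sing <- singles[singles$condition == condition, , drop = FALSE]
  ntc <- ntc_ids(library)
  ids <- library$sgrnas$sgrna_id
  S <- length(ids)
  reps <- sort(unique(ph$replicate))

  sum_m <- matrix(0, S, S, dimnames = list(ids, ids))
  nrep_m <- matrix(0L, S, S, dimnames = list(ids, ids))
  nobs_m <- matrix(0L, S, S, dimnames = list(ids, ids))
  skipped <- character()

  for (r in reps) {
    phr <- ph[ph$replicate == r, , drop = FALSE]
    sv <- sing[sing$replicate == r, , drop = FALSE]
    svec <- stats::setNames(sv$phenotype, sv$sgrna_id)

    zsum <- matrix(0, S, S, dimnames = list(ids, ids))
    zn <- matrix(0L, S, S, dimnames = list(ids, ids))

    queries <- unique(c(phr$sgrna_a, phr$sgrna_b))
    for (q in queries) {
      ia <- phr$sgrna_a == q
      ib <- phr$sgrna_b == q & phr$sgrna_a != q  # self-construct enters once
      partner <- c(phr$sgrna_b[ia], phr$sgrna_a[ib])
      y <- c(phr$phenotype[ia], phr$phenotype[ib])
      x <- unname(svec[partner])
      ok <- is.finite(x) & is.finite(y)
      if (sum(ok) < 3L) { skipped <- c(skipped, q); next }
      fit <- fit_query_model(x[ok], y[ok], min_quadratic)
      resid <- rep(NA_real_, length(partner))
      resid[ok] <- fit$residuals
      null_res <- resid[partner %in% ntc & is.finite(resid)]
      if (length(null_res) < min_null) { skipped <- c(skipped, q); next }
      s0 <- stats::sd(null_res)
      if (!is.finite(s0) || s0 == 0) { skipped <- c(skipped, q); next }
      z <- resid / s0
      use <- is.finite(z)
      qi <- match(q, ids)
      pi_ <- match(partner[use], ids)
      i <- pmin(qi, pi_)
      j <- pmax(qi, pi_)
      li <- i + (j - 1L) * S
      zs <- rowsum(z[use], li)
      at <- as.integer(rownames(zs))
      zsum[at] <- zsum[at] + zs[, 1L]
      zn[at] <- zn[at] + as.integer(rowsum(rep(1L, length(li)), li)[, 1L])
    }
    has <- zn > 0L
    sum_m[has] <- sum_m[has] + zsum[has] / zn[has]
    nrep_m[has] <- nrep_m[has] + 1L
    nobs_m <- nobs_m + zn
  }
  if (length(skipped))
    message(length(unique(skipped)),
            " query sgRNA(s) excluded (insufficient partners or null residuals)")

  scores <- sum_m / ifelse(nrep_m > 0L, nrep_m, NA_integer_)
  scores[nrep_m == 0L] <- NA_real_
  ## mirror the upper triangle so the matrix is exactly symmetric
  low <- lower.tri(scores)
  scores[low] <- t(scores)[low]
  nobs_m[low] <- t(nobs_m)[low]

  keep <- rowSums(is.finite(scores)) > 0L
  scores <- scores[keep, keep, drop = FALSE]
  nobs_m <- nobs_m[keep, keep, drop = FALSE]

  is_ntc_row <- rownames(scores) %in% ntc
  ctrl <- scores[, is_ntc_row, drop = FALSE]
  ctrl_names <- outer(rownames(scores), colnames(ctrl), paste, sep = "|")
  control_scores <- stats::setNames(as.numeric(ctrl), as.character(ctrl_names))
  ## keep each unordered control pair once
  a <- sub("\\|.*", "", names(control_scores))
  b <- sub(".*\\|", "", names(control_scores))
  keep_ctrl <- a <= b | !(a %in% ntc)
  control_scores <- control_scores[keep_ctrl & is.finite(control_scores)]

  new_gi_map(scores = scores, n_obs = nobs_m,
             control_scores = control_scores, level = "sgrna",
             condition = condition,
             channel = if (condition == cp$reference) "gamma" else "tau",
             gene_map = gene_of(library))
}

## Internal constructor for interaction maps.
new_gi_map <- function(scores, n_obs, control_scores, level, condition,
                       channel, gene_map = NULL) {
  structure(list(scores = scores, n_obs = n_obs,
                 control_scores = control_scores, level = level,
                 condition = condition, channel = channel,
                 gene_map = gene_map),
            class = "gi_map")
}

#' Aggregate an sgRNA-level interaction map to gene level
#'
#' The gene-pair score is the mean of all available unordered sgRNA-pair
#' scores between the two genes' guides (four sgRNA pairs, i.e. eight
#' ordered constructs, for two guides per gene). The diagonal holds the
#' mean over same-gene sgRNA pairs. Scores pairing a gene with each
#' individual ntc sgRNA — the ntc treated as a pseudo-gene of size 1 —
#' are computed identically and stored as `control_scores`; they define
#' the null spread used by [call_high_confidence()].
#'
#' @param sg an sgRNA-level `gi_map` from [score_sgrna_gis()].
#' @param library the `gi_library`.
#' @return A gene-level `gi_map`.
#' @export
gene_level_gis <- function(sg, library) {
  stop_if_not_class(sg, "gi_map", "sg")
  if (sg$level != "sgrna") stop("'sg' must be an sgRNA-level map")
  g <- gene_of(library)
  ids <- rownames(sg$scores)
  ## the gene universe is the library's: a gene whose sgRNAs were all
  ## excluded in this condition keeps its row, fully masked
  genes <- sort(unique(library$sgrnas$gene[!library$sgrnas$is_ntc]))
  ntc <- intersect(ids, ntc_ids(library))
  G <- length(genes)

  scores <- matrix(NA_real_, G, G, dimnames = list(genes, genes))
  nobs <- matrix(0L, G, G, dimnames = list(genes, genes))
  members <- split(ids, g[ids])

  for (i in seq_len(G)) {
    ui <- members[[genes[i]]]
    if (is.null(ui) || !length(ui)) next
    for (j in i:G) {
      uj <- members[[genes[j]]]
      if (is.null(uj) || !length(uj)) next
      sub <- sg$scores[ui, uj, drop = FALSE]
      nsub <- sg$n_obs[ui, uj, drop = FALSE]
      if (i == j) {
        keep <- upper.tri(sub, diag = TRUE)
        vals <- sub[keep]
        nvals <- nsub[keep]
      } else {
        vals <- as.numeric(sub)
        nvals <- as.integer(nsub)
      }
      fin <- is.finite(vals)
      if (any(fin)) {
        scores[i, j] <- mean(vals[fin])
        scores[j, i] <- scores[i, j]
        nobs[i, j] <- nobs[j, i] <- sum(nvals[fin])
      }
    }
  }

  ctrl <- numeric(0)
  for (n1 in ntc) {
    v <- vapply(genes, function(gn) {
      vals <- sg$scores[members[[gn]], n1]
      vals <- vals[is.finite(vals)]
      if (length(vals)) mean(vals) else NA_real_
    }, numeric(1L))
    names(v) <- paste(genes, n1, sep = "|")
    ctrl <- c(ctrl, v[is.finite(v)])
  }

  new_gi_map(scores = scores, n_obs = nobs, control_scores = ctrl,
             level = "gene", condition = sg$condition, channel = sg$channel)
}

#' Call high-confidence interactions
#'
#' An interaction is significant when its magnitude strictly exceeds
#' `n_sd` standard deviations of the map's negative-control score
#' distribution (gene-ntc scores at gene level, sgRNA-ntc at sgRNA
#' level). Negative calls are synthetic-sick, positive calls buffering.
#'
#' @param m a `gi_map`.
#' @param n_sd threshold in control standard deviations (default 4).
#' @return data frame over unordered distinct pairs: `(gene_a, gene_b,
#'   score, n_obs, sign, significant)`, with the threshold in
#'   `attr(, "threshold")`.
#' @export
call_high_confidence <- function(m, n_sd = 4) {
  stop_if_not_class(m, "gi_map", "m")
  if (!length(m$control_scores)) stop("map has no control scores")
  thr <- n_sd * stats::sd(m$control_scores)
  sc <- m$scores
  ut <- which(upper.tri(sc), arr.ind = TRUE)
  calls <- data.frame(
    gene_a = rownames(sc)[ut[, 1L]],
    gene_b = colnames(sc)[ut[, 2L]],
    score = sc[ut],
    n_obs = m$n_obs[ut],
    stringsAsFactors = FALSE
  )
  calls <- calls[is.finite(calls$score), , drop = FALSE]
  calls$sign <- ifelse(calls$score > 0, "buffering", "synthetic_sick")
  calls$significant <- abs(calls$score) > thr
  attr(calls, "threshold") <- thr
  calls
}

#' @export
print.gi_map <- function(x, ...) {
  cat(sprintf("%s-level %s interaction map, condition '%s'\n",
              x$level, x$channel, x$condition))
  cat(sprintf("  %d x %d scores (%d measured), %d control scores (sd %.3f)\n",
              nrow(x$scores), ncol(x$scores),
              sum(is.finite(x$scores[upper.tri(x$scores)])),
              length(x$control_scores), stats::sd(x$control_scores)))
  invisible(x)
}

#' @export
summary.gi_map <- function(object, n_sd = 4, ...) {
  calls <- call_high_confidence(object, n_sd)
  sig <- calls[calls$significant, , drop = FALSE]
  res <- list(
    level = object$level, condition = object$condition,
    channel = object$channel,
    n_pairs = nrow(calls),
    threshold = attr(calls, "threshold"),
    n_positive = sum(sig$score > 0),
    n_negative = sum(sig$score < 0),
    control_sd = stats::sd(object$control_scores)
  )
  class(res) <- "summary.gi_map"
  res
}

#' @export
print.summary.gi_map <- function(x, ...) {
  cat(sprintf("%s-level map, condition '%s' (%s channel)\n",
              x$level, x$condition, x$channel))
  cat(sprintf("  %d scored pairs; control sd %.3f; threshold %.3f\n",
              x$n_pairs, x$control_sd, x$threshold))
  cat(sprintf("  high-confidence: %d positive (buffering), %d negative (synthetic sick)\n",
              x$n_positive, x$n_negative))
  invisible(x)
}

#' Plot an interaction score distribution
#'
#' Histogram of pairwise interaction scores with the negative-control
#' distribution overlaid and the high-confidence thresholds marked.
#'
#' @param x a `gi_map`.
#' @param n_sd threshold in control standard deviations (default 4).
#' @param ... passed to [graphics::hist()].
#' @export
plot.gi_map <- function(x, n_sd = 4, ...) {
  sc <- x$scores[upper.tri(x$scores)]
  sc <- sc[is.finite(sc)]
  thr <- n_sd * stats::sd(x$control_scores)
  graphics::hist(sc, breaks = 50, freq = FALSE, col = "grey80",
                 border = NA, xlab = "interaction score",
                 main = sprintf("%s (%s level)", x$condition, x$level), ...)
  if (length(x$control_scores) > 1L) {
    d <- stats::density(x$control_scores)
    graphics::lines(d, col = "deeppink3", lwd = 2)
  }
  graphics::abline(v = c(-thr, thr), lty = 2, col = "grey30")
  invisible(x)
}

#' Write an interaction map as TSV
#'
#' Writes the square score matrix with row/column labels, and (optionally)
#' a long-format table `(gene_a, gene_b, score, n_obs, significant)`.
#'
#' @param m a `gi_map`.
#' @param path file path for the square matrix.
#' @param long_path optional path for the long-format calls table.
#' @param n_sd threshold used for the `significant` column (default 4).
#' @export
write_gi_map <- function(m, path, long_path = NULL, n_sd = 4) {
  stop_if_not_class(m, "gi_map", "m")
  df <- data.frame(id = rownames(m$scores), m$scores, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(long_path)) {
    calls <- call_high_confidence(m, n_sd)
    utils::write.table(calls, long_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
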