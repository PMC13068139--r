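#' Flag under-sequenced sgRNAs per condition
#'
#' An sgRNA is flagged in a condition when the median raw read count of the
#' constructs carrying it — in either cassette position, in any sample of
#' that condition (the shared T0 samples count for every condition) — falls
#' below `min_median`. Every construct containing a flagged sgRNA is
#' excluded from that condition's downstream analysis.
#'
#' @param counts constructs x samples integer matrix (raw reads).
#' @param library a `gi_library`.
#' @param min_median threshold on the median raw count (default 35).
#' @return data frame `(sgrna_id, condition, flagged)` covering every
#'   sgRNA x non-T0 condition combination.
#' @export
filter_constructs <- function(counts, library, min_median = 35) {
  stop_if_not_class(library, "gi_library", "library")
  con <- library$constructs
  counts <- counts[con$construct_id, , drop = FALSE]
  conds <- setdiff(unique(sample_condition(colnames(counts))), "T0")
  t0_cols <- colnames(counts)[sample_condition(colnames(counts)) == "T0"]
  idx_a <- split(seq_len(nrow(con)), con$sgrna_a)
  idx_b <- split(seq_len(nrow(con)), con$sgrna_b)
  sgrnas <- library$sgrnas$sgrna_id

  res <- lapply(conds, function(cond) {
    cols <- c(t0_cols,
              colnames(counts)[sample_condition(colnames(counts)) == cond])
    flagged <- vapply(sgrnas, function(s) {
      any(vapply(cols, function(cl) {
        stats::median(counts[idx_a[[s]], cl]) < min_median ||
          stats::median(counts[idx_b[[s]], cl]) < min_median
      }, logical(1L)))
    }, logical(1L))
    data.frame(sgrna_id = sgrnas, condition = cond, flagged = flagged,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, res)
}

#' Compute construct-level growth and drug phenotypes
#'
#' Converts a dual-guide counts table into per-construct, per-replicate
#' phenotypes expressed as log2 fold enrichment per population doubling:
#'
#' * gamma (untreated growth): `log2[(R_F/N_F) / (R_0/N_0)] / d_u`
#' * tau (treated growth):     `log2[(R_T/N_T) / (R_0/N_0)] / d_t`
#' * rho (drug-specific):      `log2[(R_T/N_T) / (R_F/N_F)] / (d_u - d_t)`
#'
#' where `R` is the construct's read count in the initial (`0`), final
#' untreated (`F`) or final treated (`T`) sample, `N` the median read count
#' among ntc-ntc constructs in the same sample, and `d` the cumulative
#' population doublings of the arm. Counts are first depth-normalized:
#' each sample is rescaled to a common total of `norm_total` reads, by
#' default 1000 reads per library element (the screens' standard
#' coverage), so the pseudocount acts on the familiar raw-count scale.
#' Under-sequenced sgRNAs are flagged on the raw counts
#' ([filter_constructs()]), and the pseudocount is then added to every
#' normalized count; because the rescaling target is a constant and both
#' the construct and the ntc normalizer live in the same sample, the
#' phenotype is exactly invariant to rescaling any sample's counts.
#'
#' The three formulas are algebraically linked:
#' `rho * (d_u - d_t) = tau * d_t - gamma * d_u` for every construct.
#'
#' @param counts constructs x samples integer matrix; columns labelled
#'   `T0_<rep>` and `<condition>_<rep>`.
#' @param library a `gi_library`; must contain at least one ntc-ntc
#'   construct (the normalizer).
#' @param doublings data frame `(condition, replicate, doublings)`, one
#'   entry per final sample.
#' @param reference label of the untreated condition; phenotypes of the
#'   reference are gammas, those of other conditions are taus, and rho is
#'   computed for treated conditions against the same-replicate reference
#'   arm. Defaults to the first condition in `doublings`.
#' @param pseudocount added to each depth-normalized count (default 10).
#' @param min_median raw-count filter threshold (default 35).
#' @param norm_total common per-sample total after depth normalization;
#'   the default (`NULL`) uses 1000 reads per library element.
#' @return A `construct_phenotypes` object: list with `phenotypes` (data
#'   frame `construct_id, sgrna_a, sgrna_b, condition, replicate,
#'   phenotype, rho, filtered`), `filters` (from [filter_constructs()]),
#'   `reference`, `doublings`.
#' @export
compute_construct_phenotypes <- function(counts, library, doublings,
                                         reference = NULL,
                                         pseudocount = 10, min_median = 35,
                                         norm_total = NULL) {
  stop_if_not_class(library, "gi_library", "library")
  con <- library$constructs
  missing <- setdiff(con$construct_id, rownames(counts))
  if (length(missing))
    stop(length(missing), " constructs absent from the counts table")
  counts <- counts[con$construct_id, , drop = FALSE]
  if (any(doublings$doublings <= 0)) stop("doublings must be > 0")
  reference <- reference %||% doublings$condition[1L]

  ntc_pair <- con$sgrna_a %in% ntc_ids(library) &
    con$sgrna_b %in% ntc_ids(library)
  if (!any(ntc_pair))
    stop("no ntc-ntc constructs: cannot form the phenotype normalizer")

  filters <- filter_constructs(counts, library, min_median)

  norm_total <- norm_total %||% (1000 * nrow(counts))
  totals <- colSums(counts)
  if (any(totals <= 0)) stop("every sample must have positive total counts")
  nc <- sweep(counts, 2L, totals / norm_total, "/")

  conds <- setdiff(unique(sample_condition(colnames(counts))), "T0")
  if (!reference %in% conds)
    stop("reference condition '", reference, "' not present in the counts")

  ## log2 of pseudocounted, ntc-median-normalized enrichment for one sample
  log_ratio <- function(col) {
    n <- stats::median(nc[ntc_pair, col]) + pseudocount
    log2((nc[, col] + pseudocount) / n)
  }

  d_of <- function(cond, rep) {
    d <- doublings$doublings[doublings$condition == cond &
                               doublings$replicate == rep]
    if (length(d) != 1L)
      stop(sprintf("need exactly one doublings entry for (%s, %s)", cond, rep))
    d
  }

  out <- list()
  for (cond in conds) {
    fcols <- colnames(counts)[sample_condition(colnames(counts)) == cond]
    flag <- filters$flagged[filters$condition == cond]
    names(flag) <- filters$sgrna_id[filters$condition == cond]
    con_flagged <- flag[con$sgrna_a] | flag[con$sgrna_b]
    for (fcol in fcols) {
      rep <- sample_replicate(fcol)
      t0col <- sample_label("T0", rep)
      if (!t0col %in% colnames(counts))
        stop("no T0 sample for replicate ", rep)
      d <- d_of(cond, rep)
      phen <- (log_ratio(fcol) - log_ratio(t0col)) / d

      rho <- rep(NA_real_, nrow(con))
      if (cond != reference) {
        refcol <- sample_label(reference, rep)
        d_u <- d_of(reference, rep)
        if (abs(d_u - d) > .Machine$double.eps^0.5) {
          rho <- (log_ratio(fcol) - log_ratio(refcol)) / (d_u - d)
        }
      }
      out[[length(out) + 1L]] <- data.frame(
        construct_id = con$construct_id,
        sgrna_a = con$sgrna_a, sgrna_b = con$sgrna_b,
        condition = cond, replicate = rep,
        phenotype = as.numeric(phen), rho = as.numeric(rho),
        filtered = as.logical(con_flagged),
        stringsAsFactors = FALSE, row.names = NULL
      )
    }
  }
  structure(list(phenotypes = do.call(rbind, out), filters = filters,
                 reference = reference, doublings = doublings,
                 pseudocount = pseudocount, min_median = min_median,
                 norm_total = norm_total),
            class = "construct_phenotypes")
}

#' @export
print.construct_phenotypes <- function(x, ...) {
  ph <- x$phenotypes
  cat(sprintf(
    "Construct phenotypes: %d constructs, conditions [%s] (reference: %s), %d replicates\n",
    length(unique(ph$construct_id)),
    paste(unique(ph$condition), collapse = ", "), x$reference,
    length(unique(ph$replicate))))
  cat(sprintf("  filtered: %.1f%% of construct-condition pairs\n",
              100 * mean(ph$filtered)))
  invisible(x)
}

#' Single-sgRNA phenotypes from ntc-paired constructs
#'
#' Estimates each sgRNA's single-knockdown phenotype as the mean phenotype
#' of its constructs paired with a non-targeting control, over both
#' cassette orientations — with 13 controls this is 26 independent
#' measurements per sgRNA and 52 per 2-sgRNA gene. Filtered constructs are
#' excluded; an sgRNA with no usable ntc-paired construct in a condition
#' is dropped with a warning.
#'
#' @param cp a [compute_construct_phenotypes()] result.
#' @param library the matching `gi_library`.
#' @return A `single_phenotypes` data frame: `(sgrna_id, gene, is_ntc,
#'   condition, replicate, phenotype, rho, n_measurements)`.
#' @export
single_sgrna_phenotypes <- function(cp, library) {
  stop_if_not_class(cp, "construct_phenotypes", "cp")
  ph <- cp$phenotypes[!cp$phenotypes$filtered, , drop = FALSE]
  ntc <- ntc_ids(library)
  g <- gene_of(library)

  a_ntc <- ph$sgrna_a %in% ntc
  b_ntc <- ph$sgrna_b %in% ntc
  ## each row contributes to the non-ntc side's single estimate; ntc-ntc
  ## rows contribute to both ntc sgRNAs' own (null) singles
  long <- rbind(
    data.frame(sgrna_id = ph$sgrna_a[b_ntc], condition = ph$condition[b_ntc],
               replicate = ph$replicate[b_ntc], phenotype = ph$phenotype[b_ntc],
               rho = ph$rho[b_ntc], stringsAsFactors = FALSE),
    data.frame(sgrna_id = ph$sgrna_b[a_ntc], condition = ph$condition[a_ntc],
               replicate = ph$replicate[a_ntc], phenotype = ph$phenotype[a_ntc],
               rho = ph$rho[a_ntc], stringsAsFactors = FALSE)
  )
  agg <- stats::aggregate(
    cbind(phenotype, rho) ~ sgrna_id + condition + replicate, data = long,
    FUN = mean, na.action = stats::na.pass)
  n <- stats::aggregate(phenotype ~ sgrna_id + condition + replicate,
                        data = long, FUN = length)
  agg$n_measurements <- n$phenotype[match(
    paste(agg$sgrna_id, agg$condition, agg$replicate),
    paste(n$sgrna_id, n$condition, n$replicate))]
  agg$gene <- unname(g[agg$sgrna_id])
  agg$is_ntc <- agg$sgrna_id %in% ntc

  expected <- length(unique(cp$phenotypes$sgrna_a))
  got <- length(unique(agg$sgrna_id))
  if (got < expected)
    warning(expected - got,
            " sgRNA(s) had no usable ntc-paired construct and were dropped")
  res <- agg[, c("sgrna_id", "gene", "is_ntc", "condition", "replicate",
                 "phenotype", "rho", "n_measurements")]
  class(res) <- c("single_phenotypes", "data.frame")
  res
}

#' Call hits in a single-sgRNA nominating screen
#'
#' Per targeting gene, compares the gene's sgRNA-level drug phenotypes
#' (rho, averaged over replicates per sgRNA) against the non-targeting
#' control rho distribution with a two-sided Mann-Whitney U test. A gene is
#' a hit when its mean rho strictly exceeds `rho_cut` in magnitude and the
#' p-value is strictly below `p_cut`.
#'
#' @param singles a [single_sgrna_phenotypes()] result.
#' @param condition treated condition whose rho values are tested.
#' @param rho_cut magnitude threshold on the gene-level mean rho
#'   (default 0.2, strict).
#' @param p_cut p-value threshold (default 0.02, strict).
#' @return data frame `(gene, rho, n_sgrnas, p_value, hit)` sorted by
#'   p-value.
#' @export
call_nominating_hits <- function(singles, condition, rho_cut = 0.2,
                                 p_cut = 0.02) {
  s <- singles[singles$condition == condition & !is.na(singles$rho), ,
               drop = FALSE]
  if (!nrow(s)) stop("no rho values for condition '", condition, "'")
  by_sg <- stats::aggregate(rho ~ sgrna_id + gene + is_ntc, data = s,
                            FUN = mean)
  null_rho <- by_sg$rho[by_sg$is_ntc]
  if (length(null_rho) < 2L)
    stop("need >= 2 ntc sgRNA rho values for the null distribution")

  genes <- unique(by_sg$gene[!by_sg$is_ntc])
  res <- lapply(genes, function(gn) {
    v <- by_sg$rho[by_sg$gene == gn]
    if (!length(v)) return(NULL)
    p <- suppressWarnings(
      stats::wilcox.test(v, null_rho, alternative = "two.sided")$p.value)
    data.frame(gene = gn, rho = mean(v), n_sgrnas = length(v),
               p_value = p, stringsAsFactors = FALSE)
  })
  dropped <- sum(vapply(res, is.null, logical(1L)))
  if (dropped) warning(dropped, " gene(s) had no surviving sgRNA rho values")
  res <- do.call(rbind, res)
  res$hit <- abs(res$rho) > rho_cut & res$p_value < p_cut
  res[order(res$p_value), ]
}

#' Write a phenotype table as TSV
#'
#' Long-format TSV `construct_id  condition  replicate  phenotype  rho
#' filtered`.
#'
#' @param cp a `construct_phenotypes` object.
#' @param path file path.
#' @export
write_phenotypes <- function(cp, path) {
  stop_if_not_class(cp, "construct_phenotypes", "cp")
  cols <- c("construct_id", "condition", "replicate", "phenotype", "rho",
            "filtered")
  utils::write.table(cp$phenotypes[, cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
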