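#' Simulate ground-truth effects for a dual-guide screen
#'
#' Draws a ground truth for the growth model that the phenotype estimators
#' invert: every targeting sgRNA gets a fitness effect per population
#' doubling (log2 fold-enrichment per doubling, the gamma scale), genes get
#' pairwise interaction terms in a reference condition, and a configurable
#' fraction of those interactions is rewired (re-drawn) in each
#' environmental condition — the planted differential interactions.
#'
#' Gene-level effects are drawn `Normal(0, effect_sd)`; each sgRNA of a
#' gene scatters around the gene mean with standard deviation
#' `sgrna_scatter * effect_sd`, so same-gene guides correlate without being
#' duplicates. In treated conditions the per-doubling effect (the tau
#' scale) is the reference effect plus a per-gene drug modifier drawn
#' `Normal(0, drug_effect_sd)`. A fraction `frac_interacting` of unordered
#' targeting-gene pairs receives an interaction `Normal(0, gi_effect_sd)`,
#' defined at gene level and inherited by all sgRNA pairs of the two genes
#' (eight ordered constructs for a 2-sgRNA-per-gene library). Non-targeting
#' controls have effect exactly 0 and take part in no interaction.
#'
#' @param library a [make_library()] design.
#' @param conditions character vector of condition labels; the first is the
#'   reference (untreated) condition. Labels must not contain `"_"`.
#' @param doublings population doublings per condition: either a data frame
#'   `(condition, replicate, doublings)` or a named numeric vector (one
#'   value per condition, recycled over `n_reps` replicates). Defaults to 8
#'   doublings in the reference and 3.5 in treated arms.
#' @param n_reps number of biological replicates (used when `doublings` is
#'   a vector).
#' @param effect_sd SD of gene-level fitness effects (log2/doubling).
#' @param sgrna_scatter sgRNA-level scatter as a fraction of `effect_sd`.
#' @param frac_interacting fraction of unordered gene pairs given a nonzero
#'   interaction in the reference condition.
#' @param gi_effect_sd SD of interaction terms (log2/doubling).
#' @param rewiring_frac fraction of planted interactions re-drawn in each
#'   non-reference condition (the planted rewiring events).
#' @param drug_effect_sd SD of per-gene drug modifiers in treated arms.
#' @param drug_modifiers optional list, one named numeric vector per
#'   treated condition (`gene -> modifier`), overriding the random draw for
#'   those genes.
#' @param seed optional integer for reproducibility.
#' @return A `sim_truth` object; see [sim_truth()] for the fields.
#' @export
simulate_truth <- function(library,
                           conditions = c("reference", "treated"),
                           doublings = NULL, n_reps = 2L,
                           effect_sd = 0.1, sgrna_scatter = 0.2,
                           frac_interacting = 0.1, gi_effect_sd = 0.3,
                           rewiring_frac = 0.5,
                           drug_effect_sd = effect_sd,
                           drug_modifiers = NULL, seed = NULL) {
  stop_if_not_class(library, "gi_library", "library")
  if (frac_interacting < 0 || frac_interacting > 1)
    stop("'frac_interacting' must be in [0, 1]")
  if (rewiring_frac < 0 || rewiring_frac > 1)
    stop("'rewiring_frac' must be in [0, 1]")
  if (any(grepl("_", conditions)))
    stop("condition labels must not contain '_'")
  if ("T0" %in% conditions) stop("'T0' is a reserved sample label")

  if (is.null(doublings)) {
    doublings <- stats::setNames(
      c(8, rep(3.5, length(conditions) - 1L)), conditions)
  }
  if (!is.data.frame(doublings)) {
    doublings <- data.frame(
      condition = rep(names(doublings), each = n_reps),
      replicate = rep(seq_len(n_reps), length(doublings)),
      doublings = rep(as.numeric(doublings), each = n_reps),
      stringsAsFactors = FALSE
    )
  }
  missing <- setdiff(conditions, doublings$condition)
  if (length(missing))
    stop("no doublings entry for condition(s): ",
         paste(missing, collapse = ", "))
  if (any(doublings$doublings <= 0)) stop("doublings must be > 0")

  sg <- library$sgrnas
  genes <- unique(sg$gene[!sg$is_ntc])
  reference <- conditions[1L]
  treated <- setdiff(conditions, reference)

  with_seed(seed, {
    gene_eff <- stats::setNames(stats::rnorm(length(genes), 0, effect_sd), genes)
    pt <- matrix(0, nrow(sg), length(conditions),
                 dimnames = list(sg$sgrna_id, conditions))
    targ <- !sg$is_ntc
    gamma_true <- gene_eff[sg$gene[targ]] +
      stats::rnorm(sum(targ), 0, sgrna_scatter * effect_sd)
    pt[targ, reference] <- gamma_true
    for (cond in treated) {
      mod <- stats::setNames(stats::rnorm(length(genes), 0, drug_effect_sd), genes)
      if (!is.null(drug_modifiers[[cond]])) {
        ov <- drug_modifiers[[cond]]
        mod[names(ov)] <- ov
      }
      pt[targ, cond] <- gamma_true + mod[sg$gene[targ]]
    }

    inter <- data.frame(gene_a = character(), gene_b = character(),
                        condition = character(), gi_true = numeric(),
                        rewired = logical(), stringsAsFactors = FALSE)
    if (length(genes) >= 2L && frac_interacting > 0) {
      pairs <- utils::combn(sort(genes), 2L)
      n_pick <- floor(frac_interacting * ncol(pairs))
      if (n_pick > 0L) {
        pick <- sort(sample.int(ncol(pairs), n_pick))
        base <- stats::rnorm(n_pick, 0, gi_effect_sd)
        inter <- do.call(rbind, lapply(conditions, function(cond) {
          gi <- base
          rew <- rep(FALSE, n_pick)
          if (cond != reference && rewiring_frac > 0) {
            n_rew <- floor(rewiring_frac * n_pick)
            if (n_rew > 0L) {
              idx <- sample.int(n_pick, n_rew)
              gi[idx] <- stats::rnorm(n_rew, 0, gi_effect_sd)
              rew[idx] <- TRUE
            }
          }
          data.frame(gene_a = pairs[1L, pick], gene_b = pairs[2L, pick],
                     condition = cond, gi_true = gi, rewired = rew,
                     stringsAsFactors = FALSE)
        }))
      }
    }

    sim_truth(phenotype_true = pt, interactions = inter,
              doublings = doublings, reference = reference)
  })
}

#' Construct a ground-truth object by hand
#'
#' Low-level constructor used by [simulate_truth()] and by tests that need
#' exact, hand-chosen truths. Validates that non-targeting controls (rows
#' whose id is absent or zero) are exactly zero is the caller's
#' responsibility; interactions are stored with `gene_a < gene_b`.
#'
#' @param phenotype_true numeric matrix, sgRNAs x conditions, of true
#'   log2-enrichment-per-doubling effects (gamma scale in the reference
#'   column, tau scale elsewhere).
#' @param interactions data frame `(gene_a, gene_b, condition, gi_true)`
#'   with optional `rewired` flag; symmetric pairs are canonicalized.
#' @param doublings data frame `(condition, replicate, doublings)`.
#' @param reference label of the reference condition (a column of
#'   `phenotype_true`).
#' @return A `sim_truth` object with fields `phenotype_true`,
#'   `interactions`, `doublings`, `reference`.
#' @export
sim_truth <- function(phenotype_true, interactions, doublings, reference) {
  if (!reference %in% colnames(phenotype_true))
    stop("'reference' must name a column of 'phenotype_true'")
  if (nrow(interactions)) {
    a <- pmin(interactions$gene_a, interactions$gene_b)
    b <- pmax(interactions$gene_a, interactions$gene_b)
    interactions$gene_a <- a
    interactions$gene_b <- b
    if (is.null(interactions$rewired)) interactions$rewired <- FALSE
    key <- paste(a, b, interactions$condition)
    if (anyDuplicated(key)) stop("duplicate interaction entries")
  }
  structure(list(phenotype_true = phenotype_true,
                 interactions = interactions,
                 doublings = doublings,
                 reference = reference),
            class = "sim_truth")
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf(
    "Simulated truth: %d sgRNAs, conditions [%s] (reference: %s), %d planted interactions\n",
    nrow(x$phenotype_true), paste(colnames(x$phenotype_true), collapse = ", "),
    x$reference,
    sum(x$interactions$condition == x$reference)))
  invisible(x)
}

## True summed phenotype (singles + interaction) per construct, one
## condition. Exported for round-trip tests and the simulator itself.
#' True construct phenotype under a simulated truth
#'
#' The per-doubling log2 enrichment of each construct in one condition:
#' sum of the two sgRNA effects plus the gene-pair interaction term. This
#' is the quantity the growth model exponentiates and the downstream
#' estimators recover.
#'
#' @param library a `gi_library`.
#' @param truth a `sim_truth`.
#' @param condition condition label.
#' @return named numeric vector over `library$constructs$construct_id`.
#' @export
true_construct_phenotype <- function(library, truth, condition) {
  pt <- truth$phenotype_true
  if (!condition %in% colnames(pt)) stop("unknown condition: ", condition)
  con <- library$constructs
  g <- gene_of(library)
  ph <- pt[con$sgrna_a, condition] + pt[con$sgrna_b, condition]
  int <- truth$interactions
  int <- int[int$condition == condition, , drop = FALSE]
  if (nrow(int)) {
    gi_map <- stats::setNames(int$gi_true, pair_key(int$gene_a, int$gene_b))
    key <- pair_key(g[con$sgrna_a], g[con$sgrna_b])
    hit <- match(key, names(gi_map))
    ph <- ph + ifelse(is.na(hit), 0, gi_map[ifelse(is.na(hit), 1L, hit)])
  }
  stats::setNames(as.numeric(ph), con$construct_id)
}

#' Simulate read counts for a dual-guide pooled screen
#'
#' Inverts the phenotype model to generate counts: each construct starts at
#' a lognormal abundance (`meanlog = 0`, `sdlog = abundance_sd_log`); after
#' `d` population doublings in condition `c` its abundance is multiplied by
#' `2^(phenotype * d)`, where the phenotype is the summed sgRNA effect plus
#' the planted gene-pair interaction for that condition
#' ([true_construct_phenotype()]). Sequencing is a multinomial draw of
#' `depth` reads over the constructs' relative abundances, independently
#' per sample. Replicates share no randomness beyond the initial abundance
#' vector (one library prep, independent T0 and endpoint samples).
#'
#' The default `abundance_sd_log = 0.8` keeps roughly 90% of constructs
#' within a 16-fold abundance range, matching the dispersion typical of
#' large cloned dual-guide pools.
#'
#' @param library a `gi_library`.
#' @param truth a `sim_truth` (provides conditions, doublings, effects).
#' @param depth total reads per sample (> 0).
#' @param abundance_sd_log SD (natural-log scale) of initial construct
#'   abundance.
#' @param seed optional integer; identical inputs and seed give
#'   bit-identical counts.
#' @return integer matrix of counts, constructs x samples. Sample columns
#'   are labelled `T0_<rep>` and `<condition>_<rep>`.
#' @export
simulate_counts <- function(library, truth, depth = 2e6,
                            abundance_sd_log = 0.8, seed = NULL) {
  stop_if_not_class(library, "gi_library", "library")
  stop_if_not_class(truth, "sim_truth", "truth")
  if (depth <= 0) stop("'depth' must be > 0")
  con <- library$constructs
  dbl <- truth$doublings
  conditions <- colnames(truth$phenotype_true)
  reps <- sort(unique(dbl$replicate))

  with_seed(seed, {
    x0 <- stats::rlnorm(nrow(con), 0, abundance_sd_log)
    samples <- c(sample_label("T0", reps),
                 unlist(lapply(conditions, sample_label, replicate = reps)))
    counts <- matrix(0L, nrow(con), length(samples),
                     dimnames = list(con$construct_id, samples))
    for (r in reps)
      counts[, sample_label("T0", r)] <-
        stats::rmultinom(1L, depth, x0)[, 1L]
    for (cond in conditions) {
      ph <- true_construct_phenotype(library, truth, cond)
      for (r in reps) {
        d <- dbl$doublings[dbl$condition == cond & dbl$replicate == r]
        if (length(d) != 1L)
          stop(sprintf("need exactly one doublings entry for (%s, %s)", cond, r))
        xf <- x0 * 2^(ph * d)
        counts[, sample_label(cond, r)] <-
          stats::rmultinom(1L, depth, xf)[, 1L]
      }
    }
    counts
  })
}

#' Write or read a counts table as TSV
#'
#' Plain TSV with a `construct_id` column followed by one column per
#' sample, labelled `<condition>_<replicate>` (`T0_<replicate>` for the
#' shared initial timepoint).
#'
#' @param counts integer matrix as returned by [simulate_counts()].
#' @param path file path.
#' @return `read_counts()` returns the counts matrix.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(construct_id = rownames(counts), counts,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df$construct_id
  m
}
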