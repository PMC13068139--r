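# Shared simulated screens, built once per test run. Study conditions:
# 20 genes x 2 sgRNAs + 5 ntc, two replicates, depth 2e6, 8 doublings
# untreated / 3.5 treated.

.screens <- new.env(parent = emptyenv())

screen_conditions <- c("ref", "env")
screen_doublings <- data.frame(
  condition = rep(c("ref", "env"), each = 2),
  replicate = rep(1:2, 2),
  doublings = rep(c(8, 3.5), each = 2)
)

build_screen <- function(frac_interacting, rewiring_frac, seed,
                         gi_effect_sd = 0.3, depth = 2e6,
                         n_genes = 20, n_ntc = 5) {
  lib <- make_library(sprintf("G%02d", seq_len(n_genes)),
                      sgrnas_per_gene = 2, n_ntc = n_ntc)
  truth <- simulate_truth(
    lib, conditions = screen_conditions, doublings = screen_doublings,
    effect_sd = 0.1, sgrna_scatter = 0.2,
    frac_interacting = frac_interacting, gi_effect_sd = gi_effect_sd,
    rewiring_frac = rewiring_frac, seed = seed
  )
  counts <- simulate_counts(lib, truth, depth = depth, seed = seed + 1)
  cp <- compute_construct_phenotypes(counts, lib, screen_doublings)
  singles <- single_sgrna_phenotypes(cp, lib)
  sg_ref <- score_sgrna_gis(cp, singles, lib, "ref")
  sg_env <- score_sgrna_gis(cp, singles, lib, "env")
  list(lib = lib, truth = truth, counts = counts, cp = cp,
       singles = singles, sg_ref = sg_ref, sg_env = sg_env,
       gi = gene_level_gis(sg_ref, lib), egi = gene_level_gis(sg_env, lib))
}

## no planted interactions in either condition
null_screen <- function() {
  if (is.null(.screens$null))
    .screens$null <- suppressMessages(
      build_screen(frac_interacting = 0, rewiring_frac = 0, seed = 101))
  .screens$null
}

## planted interactions, half rewired in the environmental condition
planted_screen <- function() {
  if (is.null(.screens$planted))
    .screens$planted <- suppressMessages(
      build_screen(frac_interacting = 0.1, rewiring_frac = 0.5, seed = 202))
  .screens$planted
}

## larger planted screen for recall/rewiring recovery: 40 genes give 78
## planted pairs, so measured recall reflects the method rather than the
## handful of near-zero effects any single small draw contains; depth keeps
## per-construct coverage high (~2300 reads)
recovery_screen <- function() {
  if (is.null(.screens$recovery))
    .screens$recovery <- suppressMessages(
      build_screen(frac_interacting = 0.1, rewiring_frac = 0.5, seed = 303,
                   depth = 2e7, n_genes = 40, n_ntc = 13))
  .screens$recovery
}

## small screen for oracle-equivalence tests: 4 genes x 2 + 4 ntc = 12 sgRNAs
toy_screen <- function() {
  if (is.null(.screens$toy)) {
    lib <- make_library(paste0("T", 1:4), sgrnas_per_gene = 2, n_ntc = 4)
    dbl <- data.frame(condition = rep(c("ref", "env"), each = 2),
                      replicate = rep(1:2, 2),
                      doublings = rep(c(8, 3.5), each = 2))
    truth <- simulate_truth(lib, conditions = c("ref", "env"),
                            doublings = dbl, effect_sd = 0.15,
                            frac_interacting = 0.3, seed = 7)
    counts <- simulate_counts(lib, truth, depth = 3e5, seed = 8)
    cp <- compute_construct_phenotypes(counts, lib, dbl)
    singles <- single_sgrna_phenotypes(cp, lib)
    .screens$toy <- list(lib = lib, truth = truth, counts = counts,
                         cp = cp, singles = singles, doublings = dbl)
  }
  .screens$toy
}

## counts table engineered for exact hand computation of the formulas:
## every sample total is 900, ntc-ntc medians are 100, and the single
## query construct moves 100 -> 25 over 2 doublings
hand_counts <- function() {
  lib <- make_library("G1", sgrnas_per_gene = 1, n_ntc = 2)
  ids <- lib$constructs$construct_id
  counts <- matrix(100L, length(ids), 2,
                   dimnames = list(ids, c("T0_1", "ref_1")))
  counts["G1-sg1:ntc-1", "ref_1"] <- 25L
  counts["ntc-2:ntc-2", "ref_1"] <- 175L  # keeps the sample total at 900
  list(lib = lib, counts = counts,
       doublings = data.frame(condition = "ref", replicate = 1,
                              doublings = 2))
}
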