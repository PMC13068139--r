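test_that("gamma matches the hand-computed value, with and without pseudocount", {
  h <- hand_counts()
  ## normalized totals are all 900, so normalized counts equal raw counts
  cp <- compute_construct_phenotypes(h$counts, h$lib, h$doublings,
                                     norm_total = 900)
  g <- cp$phenotypes$phenotype[cp$phenotypes$construct_id == "G1-sg1:ntc-1"]
  expect_equal(g, log2(35 / 110) / 2, tolerance = 1e-12)

  cp0 <- compute_construct_phenotypes(h$counts, h$lib, h$doublings,
                                      pseudocount = 0, norm_total = 900)
  g0 <- cp0$phenotypes$phenotype[cp0$phenotypes$construct_id == "G1-sg1:ntc-1"]
  expect_equal(g0, -1, tolerance = 1e-12)

  ## a construct tracking the ntc median has gamma exactly 0
  gn <- cp$phenotypes$phenotype[cp$phenotypes$construct_id == "ntc-1:ntc-1"]
  expect_equal(gn, 0, tolerance = 1e-12)
})

test_that("phenotypes are exactly invariant to rescaling a sample's counts", {
  h <- hand_counts()
  cp1 <- compute_construct_phenotypes(h$counts, h$lib, h$doublings)
  scaled <- h$counts
  scaled[, "ref_1"] <- scaled[, "ref_1"] * 7L
  cp2 <- compute_construct_phenotypes(scaled, h$lib, h$doublings)
  expect_equal(cp2$phenotypes$phenotype, cp1$phenotypes$phenotype,
               tolerance = 1e-12)
})

test_that("increasing the pseudocount shrinks gamma toward zero", {
  h <- hand_counts()
  gs <- sapply(c(0, 5, 10, 50), function(pc) {
    cp <- compute_construct_phenotypes(h$counts, h$lib, h$doublings,
                                       pseudocount = pc, norm_total = 900)
    cp$phenotypes$phenotype[cp$phenotypes$construct_id == "G1-sg1:ntc-1"]
  })
  expect_true(all(diff(abs(gs)) < 0))
})

test_that("rho satisfies its algebraic identity with gamma and tau", {
  scr <- toy_screen()
  ph <- scr$cp$phenotypes
  d_u <- 8; d_t <- 3.5
  env <- ph[ph$condition == "env", ]
  ref <- ph[ph$condition == "ref", ]
  ref <- ref[match(paste(env$construct_id, env$replicate),
                   paste(ref$construct_id, ref$replicate)), ]
  expect_equal(env$rho * (d_u - d_t), env$phenotype * d_t - ref$phenotype * d_u,
               tolerance = 1e-10)
})

test_that("rho is flagged undefined when treated and untreated doublings match", {
  h <- hand_counts()
  counts <- cbind(h$counts, env_1 = h$counts[, "ref_1"])
  dbl <- rbind(h$doublings,
               data.frame(condition = "env", replicate = 1, doublings = 2))
  cp <- compute_construct_phenotypes(counts, h$lib, dbl)
  expect_true(all(is.na(cp$phenotypes$rho[cp$phenotypes$condition == "env"])))
})

test_that("under-sequenced sgRNAs are flagged per condition and excluded downstream", {
  lib <- make_library(c("A", "B", "C"), sgrnas_per_gene = 1, n_ntc = 2)
  ids <- lib$constructs$construct_id
  counts <- matrix(100L, length(ids), 4,
                   dimnames = list(ids, c("T0_1", "ref_1", "env_1", "T0_2")))
  counts <- counts[, c("T0_1", "ref_1", "env_1")]
  ## push A-sg1's position-A constructs below the threshold in env only
  a_pos <- lib$constructs$sgrna_a == "A-sg1"
  counts[a_pos, "env_1"] <- 34L
  fl <- filter_constructs(counts, lib, min_median = 35)
  expect_true(fl$flagged[fl$sgrna_id == "A-sg1" & fl$condition == "env"])
  expect_false(fl$flagged[fl$sgrna_id == "A-sg1" & fl$condition == "ref"])
  expect_false(any(fl$flagged[fl$sgrna_id != "A-sg1"]))

  fl0 <- filter_constructs(counts, lib, min_median = 0)
  expect_false(any(fl0$flagged))

  dbl <- data.frame(condition = c("ref", "env"), replicate = 1,
                    doublings = c(4, 2))
  cp <- compute_construct_phenotypes(counts, lib, dbl)
  env_rows <- cp$phenotypes$condition == "env"
  has_a <- cp$phenotypes$sgrna_a == "A-sg1" | cp$phenotypes$sgrna_b == "A-sg1"
  expect_true(all(cp$phenotypes$filtered[env_rows & has_a]))
  expect_false(any(cp$phenotypes$filtered[!env_rows | !has_a]))
})

test_that("single phenotypes average all ntc pairings in both orientations", {
  lib <- make_library(c("A", "B"), sgrnas_per_gene = 2, n_ntc = 13)
  dbl <- data.frame(condition = "ref", replicate = 1, doublings = 8)
  tr <- simulate_truth(lib, conditions = "ref", doublings = dbl,
                       effect_sd = 0.1, frac_interacting = 0, seed = 21)
  cts <- simulate_counts(lib, tr, depth = 1e6, seed = 22)
  cp <- compute_construct_phenotypes(cts, lib, dbl)
  si <- single_sgrna_phenotypes(cp, lib)
  targ <- si[!si$is_ntc, ]
  expect_true(all(targ$n_measurements == 26L))  # 13 ntc x 2 orientations
  expect_equal(sum(targ$n_measurements[targ$gene == "A"]), 52L)

  ## the mean matches a direct computation for one sgRNA
  ph <- cp$phenotypes
  ntc <- lib$sgrnas$sgrna_id[lib$sgrnas$is_ntc]
  manual <- mean(ph$phenotype[(ph$sgrna_a == "A-sg1" & ph$sgrna_b %in% ntc) |
                              (ph$sgrna_b == "A-sg1" & ph$sgrna_a %in% ntc)])
  expect_equal(si$phenotype[si$sgrna_id == "A-sg1"], manual)

  ## ntc singles center on zero; estimates track the truth
  expect_lt(abs(mean(si$phenotype[si$is_ntc])), 0.02)
  expect_equal(unname(si$phenotype[match(c("A-sg1", "B-sg1"), si$sgrna_id)]),
               unname(tr$phenotype_true[c("A-sg1", "B-sg1"), "ref"]),
               tolerance = 0.05)
})

test_that("nominating hits need both a strong rho and a small p-value", {
  ## hand-built single-phenotype table: 12 ntc, two genes x 5 sgRNAs
  mk <- function(id, gene, is_ntc, rho) {
    data.frame(sgrna_id = id, gene = gene, is_ntc = is_ntc, condition = "env",
               replicate = 1, phenotype = 0, rho = rho, n_measurements = 10)
  }
  ntc <- mk(paste0("n", 1:12), "ntc", TRUE,
            seq(-0.055, 0.055, length.out = 12))
  strong <- mk(paste0("s", 1:5), "STRONG", FALSE, c(-0.50, -0.45, -0.55, -0.48, -0.52))
  nullg <- mk(paste0("q", 1:5), "NULLG", FALSE,
              seq(-0.055, 0.055, length.out = 12)[4:8])
  boundary <- mk(paste0("b", 1:5), "BOUND", FALSE, rep(0.2, 5))
  singles <- rbind(ntc, strong, nullg, boundary)

  hits <- call_nominating_hits(singles, "env")
  expect_true(hits$hit[hits$gene == "STRONG"])
  expect_false(hits$hit[hits$gene == "NULLG"])
  expect_gt(hits$p_value[hits$gene == "NULLG"], 0.5)
  ## |rho| == 0.2 exactly fails the strict threshold despite a small p
  expect_equal(hits$rho[hits$gene == "BOUND"], 0.2)
  expect_lt(hits$p_value[hits$gene == "BOUND"], 0.02)
  expect_false(hits$hit[hits$gene == "BOUND"])
})

test_that("a planted drug modifier is recovered as a nominating hit", {
  ## nominating screens use ~5 guides per gene; fewer cannot clear p < 0.02
  lib <- make_library(sprintf("N%02d", 1:8), sgrnas_per_gene = 5, n_ntc = 8)
  dbl <- data.frame(condition = rep(c("ref", "env"), each = 1),
                    replicate = 1, doublings = c(8, 3.5))
  tr <- simulate_truth(lib, conditions = c("ref", "env"), doublings = dbl,
                       effect_sd = 0.05, frac_interacting = 0,
                       drug_effect_sd = 0.02,
                       drug_modifiers = list(env = c(N01 = -0.5)),
                       seed = 31)
  cts <- simulate_counts(lib, tr, depth = 2e6, seed = 32)
  cp <- compute_construct_phenotypes(cts, lib, dbl)
  si <- single_sgrna_phenotypes(cp, lib)
  hits <- call_nominating_hits(si, "env")
  expect_true(hits$hit[hits$gene == "N01"])
})
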