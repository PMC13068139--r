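test_that("additive data fit a slope-1 line with vanishing residuals", {
  x <- seq(-0.6, 0.4, length.out = 20)
  q <- -0.25
  fit <- fit_query_model(x, q + x)
  expect_equal(unname(fit$coefficients["linear"]), 1, tolerance = 1e-9)
  expect_equal(unname(fit$coefficients["intercept"]), q, tolerance = 1e-9)
  expect_lt(max(abs(fit$residuals)), 1e-9)
})

test_that("a planted deviation appears as its own residual", {
  x <- seq(-0.5, 0.5, length.out = 50)
  y <- 0.1 + 0.9 * x - 0.3 * x^2
  y[25] <- y[25] + 1  # one interacting partner, offset delta = 1
  fit <- fit_query_model(x, y)
  expect_equal(fit$residuals[25], 1, tolerance = 0.05)
  expect_lt(max(abs(fit$residuals[-25])), 0.05)
})

test_that("small partner sets fall back to a line and tiny ones error", {
  x <- c(-0.2, 0, 0.3, 0.5)
  fit <- fit_query_model(x, 2 * x)
  expect_equal(fit$degree, 1L)
  expect_equal(unname(fit$coefficients["quadratic"]), 0)
  expect_error(fit_query_model(c(0, 1), c(0, 1)), "at least 3")
})

test_that("scoring matches an independent brute-force reimplementation", {
  scr <- toy_screen()
  m <- suppressMessages(score_sgrna_gis(scr$cp, scr$singles, scr$lib, "ref"))

  ## brute force: plain-loop quadratic fit + residual + z-score + averaging
  ph_all <- scr$cp$phenotypes
  ph_all <- ph_all[ph_all$condition == "ref" & !ph_all$filtered, ]
  si <- scr$singles[scr$singles$condition == "ref", ]
  ntc <- scr$lib$sgrnas$sgrna_id[scr$lib$sgrnas$is_ntc]
  ids <- scr$lib$sgrnas$sgrna_id

  rep_mats <- list()
  for (r in sort(unique(ph_all$replicate))) {
    ph <- ph_all[ph_all$replicate == r, ]
    sv <- si[si$replicate == r, ]
    zsum <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
    zn <- zsum
    for (q in ids) {
      xs <- c(); ys <- c(); ps <- c()
      for (k in seq_len(nrow(ph))) {
        if (ph$sgrna_a[k] == q) p <- ph$sgrna_b[k]
        else if (ph$sgrna_b[k] == q && ph$sgrna_a[k] != q) p <- ph$sgrna_a[k]
        else next
        s <- sv$phenotype[sv$sgrna_id == p]
        if (length(s) != 1 || !is.finite(s)) next
        xs <- c(xs, s); ys <- c(ys, ph$phenotype[k]); ps <- c(ps, p)
      }
      if (length(xs) < 3) next
      fit <- if (length(xs) >= 5) lm(ys ~ xs + I(xs^2)) else lm(ys ~ xs)
      res <- residuals(fit)
      s0 <- sd(res[ps %in% ntc])
      if (!is.finite(s0) || s0 == 0 || sum(ps %in% ntc) < 2) next
      z <- res / s0
      for (k in seq_along(z)) {
        p <- ps[k]
        if (p == q) {
          zsum[q, q] <- zsum[q, q] + z[k]; zn[q, q] <- zn[q, q] + 1
        } else {
          zsum[q, p] <- zsum[q, p] + z[k]; zn[q, p] <- zn[q, p] + 1
          zsum[p, q] <- zsum[p, q] + z[k]; zn[p, q] <- zn[p, q] + 1
        }
      }
    }
    mr <- zsum / zn
    mr[zn == 0] <- NA
    rep_mats[[as.character(r)]] <- mr
  }
  stack <- simplify2array(rep_mats)
  brute <- apply(stack, 1:2, function(v) {
    v <- v[is.finite(v)]
    if (length(v)) mean(v) else NA_real_
  })

  got <- m$scores
  expect_equal(got, brute[rownames(got), colnames(got)], tolerance = 1e-9)
})

test_that("the score matrix is exactly symmetric", {
  scr <- toy_screen()
  m <- suppressMessages(score_sgrna_gis(scr$cp, scr$singles, scr$lib, "ref"))
  expect_identical(m$scores, t(m$scores))
})

test_that("gene-level scores are plain means of sgRNA-pair scores", {
  ids <- c("A-sg1", "A-sg2", "B-sg1", "B-sg2", "ntc-1", "ntc-2")
  set.seed(5)
  sc <- matrix(rnorm(36), 6, 6, dimnames = list(ids, ids))
  sc[lower.tri(sc)] <- t(sc)[lower.tri(sc)]
  lib <- make_library(c("A", "B"), sgrnas_per_gene = 2, n_ntc = 2)
  sg <- girewire:::new_gi_map(
    scores = sc, n_obs = matrix(1L, 6, 6, dimnames = dimnames(sc)),
    control_scores = numeric(0), level = "sgrna", condition = "ref",
    channel = "gamma", gene_map = girewire:::gene_of(lib))
  gm <- gene_level_gis(sg, lib)

  ## 2x2 sgRNAs -> four unordered sgRNA pairs per gene pair
  expect_equal(gm$scores["A", "B"],
               mean(c(sc["A-sg1", "B-sg1"], sc["A-sg1", "B-sg2"],
                      sc["A-sg2", "B-sg1"], sc["A-sg2", "B-sg2"])))
  ## diagonal: same-gene pairs including guide self-pairs
  expect_equal(gm$scores["A", "A"],
               mean(c(sc["A-sg1", "A-sg1"], sc["A-sg1", "A-sg2"],
                      sc["A-sg2", "A-sg2"])))
  expect_identical(gm$scores, t(gm$scores))
  ## gene-ntc controls: each ntc is a pseudo-gene of size one
  expect_equal(unname(gm$control_scores["A|ntc-1"]),
               mean(sc[c("A-sg1", "A-sg2"), "ntc-1"]))
  expect_equal(length(gm$control_scores), 4L)

  ## constant sgRNA scores collapse to that constant
  sc2 <- matrix(0.7, 6, 6, dimnames = dimnames(sc))
  sg2 <- girewire:::new_gi_map(sc2, matrix(1L, 6, 6, dimnames = dimnames(sc)),
                               numeric(0), "sgrna", "ref", "gamma",
                               girewire:::gene_of(lib))
  expect_true(all(gene_level_gis(sg2, lib)$scores == 0.7))
})

test_that("high-confidence calls use a strict threshold on the control spread", {
  genes <- paste0("g", 1:4)
  ctrl <- rep(c(-1, 1), 10)
  thr <- 4 * sd(ctrl)
  sc <- matrix(0, 4, 4, dimnames = list(genes, genes))
  sc["g1", "g2"] <- sc["g2", "g1"] <- thr          # exactly at the threshold
  sc["g1", "g3"] <- sc["g3", "g1"] <- thr + 0.1
  sc["g2", "g3"] <- sc["g3", "g2"] <- -(thr + 0.1)
  m <- girewire:::new_gi_map(sc, matrix(1L, 4, 4), ctrl, "gene", "ref", "gamma")
  calls <- call_high_confidence(m, n_sd = 4)
  expect_equal(attr(calls, "threshold"), thr)
  k <- function(a, b) calls[calls$gene_a == a & calls$gene_b == b, ]
  expect_false(k("g1", "g2")$significant)   # boundary is not a call
  expect_true(k("g1", "g3")$significant)
  expect_true(k("g2", "g3")$significant)
  expect_equal(k("g1", "g3")$sign, "buffering")
  expect_equal(k("g2", "g3")$sign, "synthetic_sick")
})

test_that("null-data control scores are centered and calls symmetric in sign", {
  scr <- null_screen()
  expect_lt(abs(mean(scr$gi$control_scores)), 0.25)
  calls <- call_high_confidence(scr$gi, n_sd = 4)
  ## positive and negative scores are balanced under the null
  expect_gt(binom.test(sum(calls$score > 0), nrow(calls))$p.value, 1e-4)
  expect_lt(abs(mean(calls$score)), 0.25)
})

test_that("planted interactions are recovered with the right sign and rank order", {
  scr <- planted_screen()
  tr <- scr$truth
  planted <- tr$interactions[tr$interactions$condition == "ref", ]
  got <- mapply(function(a, b) scr$gi$scores[a, b],
                planted$gene_a, planted$gene_b)
  ## sign agreement for clearly nonzero planted effects
  big <- abs(planted$gi_true) > 0.1
  expect_true(all(sign(got[big]) == sign(planted$gi_true[big])))
  ## rank agreement across planted pairs
  expect_gt(cor(got, planted$gi_true, method = "spearman"), 0.7)
})
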