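test_that("cpm present calls follow the 0.5-cpm-in-3-samples rule", {
  # library size 2e6 in every sample so that 1 count = 0.5 cpm exactly
  doses <- rep(c(0, 2, 4, 8), each = 4)
  n <- length(doses)
  target <- 2e6
  passing <- rbind(
    pass3of4 = c(2, 2, 2, 0, rep(0, 12)),       # cpm 1,1,1,0 in dose 0
    boundary = c(1, 1, 1, 0, rep(0, 12)),       # cpm exactly 0.5 in 3 samples
    allzero  = rep(0, n),
    twoonly  = c(2, 2, 0, 0, rep(0, 12)))       # only 2 samples pass
  filler <- target - colSums(passing)
  m <- rbind(passing, filler = filler)
  rownames(m) <- c(rownames(passing), "filler")
  colnames(m) <- paste0("S", 1:n)
  ds <- dose_response_set(m, doses, "rnaseq", "counts")
  pc <- present_call_counts(ds, cpm_threshold = 0.5, min_samples = 3)
  expect_true(pc[["pass3of4"]])
  expect_true(pc[["boundary"]])                  # >= is inclusive
  expect_false(pc[["allzero"]])
  expect_false(pc[["twoonly"]])
  ds_log <- ds; ds_log$value_scale <- "log2_intensity"
  expect_error(present_call_counts(ds_log), "counts-scale")
})

test_that("intensity present calls use background mean + k SD with the all-but-one quorum", {
  bg_m <- 4; bg_sd <- 0.5
  ds <- make_tiny_dset(list(
    at_bg     = rep(4, 8),
    above     = rep(4 + 4 * 0.5, 8),
    boundary  = rep(4 + 3 * 0.5, 8),
    one_group = c(6, 6, rep(4, 6))))            # both samples of dose 0 pass
  pc <- present_call_intensity(ds, bg_m, bg_sd, multiplier = 3)
  expect_false(pc[["at_bg"]])
  expect_true(pc[["above"]])
  expect_true(pc[["boundary"]])                  # inclusive threshold
  expect_true(pc[["one_group"]])
  expect_error(present_call_intensity(ds, bg_m, -1), "non-negative")
})

test_that("vectorised ANOVA matches the classical aov computation", {
  ds <- make_tiny_dset(list(g1 = c(1, 2, 3, 4, 5, 6, 7, 8),
                            g2 = c(5, 5.5, 5.2, 4.8, 5.1, 5.3, 4.9, 5.4)))
  p <- anova_pvalues(ds)
  for (g in c("g1", "g2")) {
    fit <- stats::aov(v ~ factor(d),
                      data = data.frame(v = ds$values[g, ], d = ds$doses))
    p_oracle <- summary(fit)[[1]][["Pr(>F)"]][1]
    expect_equal(unname(p[g]), p_oracle, tolerance = 1e-12)
  }
})

test_that("ANOVA edge cases: equal means give p = 1, scaling leaves p unchanged", {
  ds <- make_tiny_dset(list(flat = c(1, 3, 1, 3, 1, 3, 1, 3),
                            slope = c(0, 0.2, 1, 1.1, 2, 2.2, 3, 3.1)))
  p <- anova_pvalues(ds)
  expect_equal(unname(p["flat"]), 1)             # F = 0
  ds2 <- ds; ds2$values <- 2 * ds$values
  expect_equal(anova_pvalues(ds2), p)
  const <- make_tiny_dset(list(c1 = rep(2, 8)))
  expect_equal(unname(anova_pvalues(const)["c1"]), 1)
})

test_that("BH adjustment equals the brute-force step-up definition", {
  bh_brute <- function(p) {                       # independent oracle
    n <- length(p); o <- order(p, decreasing = TRUE)
    ro <- order(o)
    out <- pmin(1, cummin(n / (n:1) * p[o]))[ro]
    out
  }
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(42)
  for (i in 1:20) {
    p <- runif(sample(1:50, 1))
    expect_equal(bh_adjust(p), bh_brute(p))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("signed fold changes follow the negative-reciprocal convention", {
  ds <- make_tiny_dset(list(up = c(0, 0, 1, 1, 2, 2, 3, 3),
                            down = c(0, 0, -1, -1, -2, -2, -3, -3),
                            flat = rep(5, 8)))
  fc <- fold_changes(ds)
  expect_equal(unname(fc["up", ]), c(1, 2, 4, 8))
  expect_equal(unname(fc["down", ]), c(1, -2, -4, -8))
  expect_equal(unname(fc["flat", ]), rep(1, 4))
})

test_that("delta-Ct fold changes implement the delta-delta-Ct method", {
  # ddCt = -1 at every dose -> FC = 2^(-ddCt) = +2
  ds <- make_tiny_dset(list(g = c(5, 5, 4, 4, 4, 4, 4, 4)),
                       platform = "qpcr", scale = "delta_ct")
  fc <- fold_changes(ds)
  expect_equal(unname(fc["g", ]), c(1, 2, 2, 2))
})

test_that("pairwise control-comparison p-values match t.test", {
  set.seed(9)
  ds <- make_tiny_dset(list(g = rnorm(12)), doses = rep(c(0, 2, 4), each = 4))
  gs <- gene_stats(ds)
  for (d in c("2", "4")) {
    oracle <- stats::t.test(ds$values[1, ds$doses == as.numeric(d)],
                            ds$values[1, ds$doses == 0],
                            var.equal = TRUE)$p.value
    expect_equal(unname(gs$pairwise_p["g", d]), oracle, tolerance = 1e-12)
  }
})

test_that("filter tiers are nested and the DEG rule adds the fold-change cut", {
  set.seed(31)
  cfg <- sim_config(n_genes = 400, seed = 31)
  st <- simulate_platform_study(cfg, "microarray")
  gs <- gene_stats(st$dset)
  sel <- select_genes(gs)
  expect_true(all(sel$fdr %in% sel$anova))
  expect_true(all(sel$anova %in% sel$none))
  expect_true(all(sel$deg %in% sel$fdr))
  # a gene passing FDR but with FC below threshold is not a DEG
  tab <- gs$table
  weak <- tab$gene[tab$fdr_p < 0.05 & tab$max_abs_fc < 1.5]
  if (length(weak)) expect_false(any(weak %in% sel$deg))
})

test_that("under the null the ANOVA tier retains about alpha of the genes", {
  cfg <- sim_config(n_genes = 2000, frac_responders = 0, seed = 77)
  st <- simulate_platform_study(cfg, "microarray")
  gs <- gene_stats(st$dset)
  frac <- mean(gs$table$anova_p < 0.05)
  expect_lt(abs(frac - 0.05), 0.015)
})
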