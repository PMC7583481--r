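# Differential-PTM statistics: linear model, FDR, tiers, clustering.

make_sheet <- function(n_per = 4, conditions = c("wt", "mut"),
                       batches = "d1") {
  data.frame(
    sample = paste0("s", seq_len(n_per * length(conditions))),
    condition = rep(conditions, each = n_per),
    batch = rep(batches, length.out = n_per * length(conditions)),
    stringsAsFactors = FALSE)
}

make_ratios <- function(sheet, marks, f = function(cond) 0.1) {
  do.call(rbind, lapply(seq_len(nrow(sheet)), function(i)
    data.frame(sample = sheet$sample[i], mark = marks,
               ratio = f(sheet$condition[i]),
               stringsAsFactors = FALSE)))
}

test_that("single-batch contrast p-value equals the pooled t-test to 1e-10", {
  set.seed(41)
  sheet <- make_sheet(5)
  ratios <- make_ratios(sheet, "H3K9me2",
                        f = function(cond) stats::runif(1, 0.05, 0.5))
  res <- fit_mark_model(ratios, sheet, list(c("mut", "wt")))
  d <- merge(ratios, sheet, by = "sample")
  tt <- stats::t.test(log2(d$ratio[d$condition == "mut"]),
                      log2(d$ratio[d$condition == "wt"]), var.equal = TRUE)
  expect_lt(abs(res$p - tt$p.value), 1e-10)
  expect_equal(res$log2fc,
               mean(log2(d$ratio[d$condition == "mut"])) -
                 mean(log2(d$ratio[d$condition == "wt"])), tolerance = 1e-10)
})

test_that("a constant batch offset leaves contrast estimates unchanged", {
  set.seed(42)
  sheet <- make_sheet(4, batches = c("d1", "d2"))
  base <- stats::runif(8, 0.1, 0.4)
  ratios <- data.frame(sample = sheet$sample, mark = "H3K18ac", ratio = base)
  res1 <- fit_mark_model(ratios, sheet, list(c("mut", "wt")))
  shifted <- ratios
  shifted$ratio[sheet$batch == "d2"] <- shifted$ratio[sheet$batch == "d2"] * 4
  res2 <- fit_mark_model(shifted, sheet, list(c("mut", "wt")))
  expect_equal(res1$log2fc, res2$log2fc, tolerance = 1e-9)
})

test_that("condition confounded with batch is an explicit error", {
  sheet <- make_sheet(3, batches = c("d1"))
  sheet$batch <- ifelse(sheet$condition == "wt", "d1", "d2")
  ratios <- make_ratios(sheet, "H3K9ac",
                        f = function(cond) stats::runif(1, 0.1, 0.5))
  expect_error(fit_mark_model(ratios, sheet, list(c("mut", "wt"))),
               "confounded")
})

test_that("zero-variance marks are dropped with a warning", {
  sheet <- make_sheet(3)
  ratios <- rbind(make_ratios(sheet, "flat", f = function(cond) 0.2),
                  make_ratios(sheet, "varies",
                              f = function(cond) stats::runif(1, 0.1, 0.5)))
  expect_warning(res <- fit_mark_model(ratios, sheet, list(c("mut", "wt"))),
                 "zero variance")
  expect_equal(unique(res$mark), "varies")
})

test_that("permuting sample order changes no estimate", {
  set.seed(43)
  sheet <- make_sheet(4, batches = c("d1", "d2"))
  ratios <- make_ratios(sheet, c("m1", "m2"),
                        f = function(cond) stats::runif(2, 0.05, 0.5))
  res1 <- fit_mark_model(ratios, sheet, list(c("mut", "wt")))
  perm <- sample(nrow(ratios))
  res2 <- fit_mark_model(ratios[perm, ], sheet[sample(nrow(sheet)), ],
                         list(c("mut", "wt")))
  expect_equal(res1[order(res1$mark), ], res2[order(res2$mark), ],
               tolerance = 1e-12)
})

test_that("BH q-values match hand computation and are monotone", {
  expect_equal(adjust_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_fdr(rep(1, 5)), rep(1, 5))
  expect_equal(adjust_fdr(0.037), 0.037)
  # step-up: q(i) = min over j >= i of p(j) * m / j, capped at 1
  set.seed(44)
  p <- stats::runif(50)
  q <- adjust_fdr(p)
  o <- order(p)
  expect_true(all(diff(q[o]) >= -1e-12))
  m <- length(p)
  q_hand <- rev(cummin(rev(p[o] * m / seq_len(m))))
  expect_equal(q[o], pmin(q_hand, 1))
  expect_error(adjust_fdr(c(0.5, 1.2)), "0, 1")
  # Storey variant never exceeds BH
  expect_true(all(adjust_fdr(p, method = "storey") <= adjust_fdr(p) + 1e-12))
})

test_that("significance tiers reproduce the heatmap star bins", {
  expect_equal(significance_tiers(c(0.2, 0.08, 0.03, 0.005, 5e-4, 5e-5)),
               c("", "*", "**", "***", "****", "*****"))
  expect_equal(significance_tiers(c(0.1, 0.05, 0.01, 0.001, 1e-4)),
               c("*", "**", "***", "****", "*****"))
})

test_that("null simulations give nominal type-I error at alpha 0.05", {
  sheet <- make_sheet(4)
  n <- nrow(sheet)
  rej <- vapply(1:1000, function(i) {
    set.seed(20000 + i)
    ratios <- data.frame(sample = sheet$sample, mark = "m",
                         ratio = exp(stats::rnorm(n, log(0.2), 0.4)))
    fit_mark_model(ratios, sheet, list(c("mut", "wt")))$p < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})

test_that("hierarchical clustering matches a brute-force oracle", {
  # O(n^3) complete-linkage agglomeration oracle
  brute_heights <- function(mat) {
    d <- as.matrix(stats::dist(mat))
    active <- as.list(seq_len(nrow(mat)))
    heights <- numeric(0)
    while (length(active) > 1L) {
      best <- c(Inf, NA, NA)
      for (i in seq_along(active)) for (j in seq_len(i - 1L)) {
        h <- max(d[active[[i]], active[[j]]])
        if (h < best[1]) best <- c(h, j, i)
      }
      heights <- c(heights, best[1])
      merged <- c(active[[best[2]]], active[[best[3]]])
      active <- active[-c(best[2], best[3])]
      active[[length(active) + 1L]] <- merged
    }
    heights
  }
  set.seed(45)
  mat <- matrix(stats::rnorm(24), nrow = 12)
  rownames(mat) <- paste0("mark", 1:12)
  cl <- cluster_marks(mat)
  expect_equal(sort(cl$height), sort(brute_heights(mat)), tolerance = 1e-9)
  # identical rows merge first at height zero
  mat2 <- rbind(a = c(1, 1), b = c(1, 1), c = c(9, 9))
  cl2 <- cluster_marks(mat2)
  expect_equal(cl2$height[1], 0)
  # the identical pair ends up adjacent in the leaf ordering
  expect_equal(abs(diff(match(c("a", "b"), cl2$order))), 1L)
  # collinear points 0, 1, 10: the near pair merges before the far point
  mat3 <- cbind(c(0, 1, 10))
  rownames(mat3) <- c("p0", "p1", "p10")
  cl3 <- cluster_marks(mat3)
  expect_equal(cl3$height, c(1, 10))
  expect_error(cluster_marks(rbind(c(1, NA), c(0, 1))), "non-finite")
  imp <- cluster_marks(rbind(c(1, NA), c(0, 1)), impute = TRUE)
  expect_length(imp$height, 1L)
})
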