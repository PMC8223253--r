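# Aligned rank transform, Holm correction, descriptives

toy_2x2 <- function(y = 1:4) {
  data.frame(A = c("a1", "a1", "a2", "a2"), B = c("b1", "b2", "b1", "b2"),
             avg_energy = y, stringsAsFactors = FALSE)
}

test_that("alignment matches the hand-computed cell-means decomposition", {
  # 1 observation/cell, responses 1,2,3,4: A-aligned values are (-1,-1,1,1)
  ar <- align_and_rank(toy_2x2(), c("A", "B"), "A")
  expect_equal(ar$aligned, c(-1, -1, 1, 1))
  # B-aligned: mu_B - grand = (-0.5, 0.5)
  arB <- align_and_rank(toy_2x2(), c("A", "B"), "B")
  expect_equal(arB$aligned, c(-0.5, 0.5, -0.5, 0.5))
  # interaction-aligned on an additive table: all zeros
  arAB <- align_and_rank(toy_2x2(), c("A", "B"), "A:B")
  expect_equal(arAB$aligned, rep(0, 4))
  expect_equal(length(unique(arAB$ranks)), 1)  # all mid-ranks equal

  # additive design (pure main effects, no interaction): the
  # interaction-aligned column has equal per-cell means
  d <- toy_2x2()[rep(1:4, each = 6), ]
  d$avg_energy <- ifelse(d$A == "a2", 3, 0) + ifelse(d$B == "b2", 1, 0) +
    rep(c(-0.5, 0.5), 12)  # within-cell spread, balanced so means are exact
  arI <- align_and_rank(d, c("A", "B"), "A:B")
  cm <- tapply(arI$aligned, interaction(d$A, d$B), mean)
  expect_lt(max(abs(cm - mean(cm))), 1e-9)

  expect_error(align_and_rank(toy_2x2()[1:3, ], c("A", "B"), "A"),
               "empty design cell")
})

test_that("all-equal responses align to zero everywhere", {
  d <- toy_2x2(rep(7, 4))
  for (e in c("A", "B", "A:B")) {
    ar <- align_and_rank(d, c("A", "B"), e)
    expect_equal(ar$aligned, rep(0, 4))
  }
})

test_that("the ART diagnostic vanishes for non-target effects", {
  set.seed(2)
  d <- expand.grid(A = c("a1", "a2"), B = c("b1", "b2", "b3"),
                   rep = 1:8, stringsAsFactors = FALSE)
  d$avg_energy <- ifelse(d$A == "a2", 2, 0) + rnorm(nrow(d))
  dg <- art_diagnostics(d, between = c("A", "B"))
  expect_true(all(dg < 0.1))
})

test_that("holm_adjust matches the step-down definition and the oracle", {
  expect_equal(holm_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(holm_adjust(0.2), 0.2)
  expect_equal(holm_adjust(rep(1, 5)), rep(1, 5))
  expect_error(holm_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(3)
  for (r in 1:25) {
    p <- runif(sample(1:12, 1))^sample(1:3, 1)
    expect_equal(holm_adjust(p), oracle_holm(p))
    expect_equal(holm_adjust(p), p.adjust(p, method = "holm"))
    expect_true(all(holm_adjust(p) >= p))
  }
})

test_that("single-factor ART agrees with Mann-Whitney and is rank-invariant", {
  set.seed(4)
  for (r in 1:3) {
    d <- data.frame(g = rep(c("x", "y"), each = 30),
                    subject = paste0("s", 1:60),
                    avg_energy = c(rnorm(30), rnorm(30, 0.4)))
    res <- art_anova(d, between = "g", response = "avg_energy")
    pw <- wilcox.test(avg_energy ~ g, data = d, exact = FALSE)$p.value
    expect_lt(abs(res$effects$p[1] - pw), 0.02)
    # strictly monotone transform leaves the single-factor ART F unchanged
    d2 <- d; d2$avg_energy <- exp(d$avg_energy)
    res2 <- art_anova(d2, between = "g", response = "avg_energy")
    expect_equal(res2$effects$F, res$effects$F, tolerance = 1e-12)
  }
})

test_that("mixed-design art_anova reports every effect with valid Holm p", {
  set.seed(5)
  subj <- paste0("s", 1:16)
  d <- expand.grid(subject = subj, state = c("wake", "sleep"),
                   band = c("gamma", "ripple", "fast_ripple"),
                   stringsAsFactors = FALSE)
  d$group <- ifelse(match(d$subject, subj) <= 8, "IS", "NC")
  d$avg_energy <- rnorm(nrow(d)) +
    ifelse(d$state == "wake", 1.5, 0) + rnorm(16)[match(d$subject, subj)]
  res <- art_anova(d, between = "group", within = c("state", "band"),
                   subject = "subject")
  eff <- res$effects
  expect_equal(nrow(eff), 7)
  expect_true(all(eff$p_holm >= eff$p - 1e-12))
  expect_true(all(eff$p_holm <= 1))
  expect_true(all(eff$df1 >= 1 & eff$df2 >= 1))
  # the injected state main effect dominates
  expect_lt(eff$p[eff$effect == "state"], 0.001)
  # unbalanced between cells warn
  expect_warning(art_anova(d[d$subject != "s1", ], between = "group",
                           within = c("state", "band"), subject = "subject"),
                 "unbalanced")
})

test_that("posthoc_pairwise produces k(k-1)/2 contrasts and finds directions", {
  set.seed(6)
  subj <- paste0("s", 1:20)
  d <- expand.grid(subject = subj, state = c("wake", "sleep"),
                   band = c("gamma", "ripple"), stringsAsFactors = FALSE)
  d$group <- "IS"
  d$avg_energy <- rnorm(nrow(d)) + ifelse(d$state == "wake", 2, 0)
  res <- art_anova(d, between = character(), within = c("state", "band"),
                   subject = "subject",
                   effects = c("state", "band", "state:band"))
  ph <- posthoc_pairwise(res, "state:band")
  expect_equal(nrow(ph), choose(4, 2))
  expect_true(all(ph$p_holm >= ph$p - 1e-12))
  i <- which((ph$cell_a == "wake:gamma" & ph$cell_b == "sleep:gamma") |
               (ph$cell_a == "sleep:gamma" & ph$cell_b == "wake:gamma"))
  expect_length(i, 1)
  est <- if (ph$cell_a[i] == "wake:gamma") ph$estimate[i] else -ph$estimate[i]
  expect_gt(est, 0)
  expect_lt(ph$p_holm[i], 0.05)
  ph2 <- posthoc_pairwise(res, "state:band",
                          cells = list(c("wake:gamma", "sleep:gamma")))
  expect_equal(nrow(ph2), 1)
  expect_error(posthoc_pairwise(res, "state:band", cells = "nope:x"),
               "unknown cell")
})

test_that("describe and paired_compare follow the declared conventions", {
  expect_equal(describe(1:9), c(median = 5, q1 = 3, q3 = 7))
  pc <- paired_compare(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(pc$p, 1)
  expect_equal(pc$statistic, 0)
  expect_error(paired_compare(1:4, 1:5), "length mismatch")
  expect_error(paired_compare(1:2, 2:3), "at least 3")

  # Gaussian shift delta = 1, sigma = 1, n = 16: paired t chosen >= 90%,
  # tiny mean p
  set.seed(7)
  chose_t <- 0; ps <- numeric(100)
  for (r in 1:100) {
    before <- rnorm(16)
    after <- before + 1 + rnorm(16)
    out <- paired_compare(before, after)
    if (out$test == "paired t") chose_t <- chose_t + 1
    ps[r] <- out$p
  }
  expect_gte(chose_t, 90)
  expect_lt(mean(ps), 0.01)
})
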