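# Mixed-effects comparison layer and morphology ANOVA.

make_monaural <- function(effects, seed, n_per_group = 8,
                          design = default_design()) {
  co <- synth_cohort(n_per_group, design = design, effects = effects,
                     conditions = cohort_conditions(itds = NULL,
                                                    frequencies_khz = NULL),
                     n_reps = 500, mode = "trace", seed = seed)
  analyze_cohort(co)$monaural
}

test_that("the mixed model recovers an injected wave IV deficit", {
  tab <- make_monaural(group_effects(
    wave4_amp_multiplier = c("female:Fmr1" = 0.7), animal_sd_av = 0.1),
    seed = 1)
  fit <- fit_mixed_model(tab, "amplitude_av", "wave")
  expect_false(fit$singular)
  ct <- pairwise_emmeans(fit, by = "sex", at = list(wave = "IV"))
  row <- ct[ct$contrast == "B6 - Fmr1" & ct$sex == "female", ]
  # generative deficit is 0.3 aV (base 1.0 at the 90 dB click, times 0.7)
  expect_lt(abs(row$estimate - 0.3), 2 * row$SE)
  expect_lt(row$p_adj, 0.05)
  expect_identical(row$adjust, "tukey")
  expect_identical(row$stars %in% c("*", "**", "***"), TRUE)
  # raw and adjusted p-values are both carried
  expect_true(all(ct$p_raw <= ct$p_adj + 1e-12))
})

test_that("zero animal variance is fitted as a flagged singular model", {
  tab <- make_monaural(null_effects(animal_sd_av = 0), seed = 3)
  fit <- fit_mixed_model(tab, "amplitude_av", "wave")
  expect_true(fit$singular)
  vc <- as.data.frame(lme4::VarCorr(fit$fit))
  expect_lt(vc$sdcor[vc$grp == "animal"], 1e-3)
})

test_that("a full factor grid yields all three genotype contrasts per sex", {
  full <- expand.grid(sex = c("female", "male"),
                      genotype = c("B6", "Fmr1", "Fmr1 het"),
                      stringsAsFactors = FALSE)
  tab <- make_monaural(group_effects(animal_sd_av = 0.1), seed = 5,
                       n_per_group = 3, design = full)
  fit <- fit_mixed_model(tab, "amplitude_av", "wave")
  ct <- pairwise_emmeans(fit, by = "sex", at = list(wave = "I"))
  expect_identical(nrow(ct), 6L)          # C(3,2) per sex
  expect_identical(as.vector(table(ct$sex)), c(3L, 3L))
  # no generative group differences: estimates consistent with zero
  expect_true(all(abs(ct$estimate) < 3.5 * ct$SE))
  # and sex contrasts within genotype are available from the same fit
  ct2 <- pairwise_emmeans(fit, by = "genotype", at = list(wave = "I"))
  expect_identical(nrow(ct2), 3L)
})

test_that("marginal contrasts are invariant to factor reference recoding", {
  tab <- make_monaural(group_effects(
    wave4_amp_multiplier = c("female:Fmr1" = 0.7), animal_sd_av = 0.1),
    seed = 7)
  fit1 <- fit_mixed_model(tab, "amplitude_av", "wave")
  tab2 <- tab
  tab2$genotype <- factor(tab2$genotype,
                          levels = c("Fmr1 het", "Fmr1", "B6"))
  fit2 <- fit_mixed_model(tab2, "amplitude_av", "wave")
  g1 <- pairwise_emmeans(fit1, by = "sex", at = list(wave = "IV"))
  g2 <- pairwise_emmeans(fit2, by = "sex", at = list(wave = "IV"))
  e1 <- g1[g1$contrast == "B6 - Fmr1" & g1$sex == "female", "estimate"]
  e2 <- g2[g2$contrast %in% c("B6 - Fmr1", "Fmr1 - B6") &
             g2$sex == "female", ]
  e2v <- ifelse(e2$contrast == "Fmr1 - B6", -e2$estimate, e2$estimate)
  expect_equal(e1, e2v, tolerance = 1e-6)
})

test_that("dropping an inert litter term barely moves genotype contrasts", {
  diffs <- c()
  for (s in 1:5) {
    tab <- make_monaural(group_effects(animal_sd_av = 0.1), seed = 100 + s,
                         n_per_group = 4)
    ct_with <- pairwise_emmeans(
      fit_mixed_model(tab, "amplitude_av", "wave"),
      by = "sex", at = list(wave = "IV"))
    tab_no <- tab[, setdiff(names(tab), "litter")]
    ct_without <- pairwise_emmeans(
      fit_mixed_model(tab_no, "amplitude_av", "wave"),
      by = "sex", at = list(wave = "IV"))
    diffs <- c(diffs, abs(ct_with$estimate - ct_without$estimate) /
                 ct_with$SE)
  }
  expect_lt(mean(diffs), 0.5)
})

test_that("rows with missing responses are dropped, never imputed", {
  tab <- make_monaural(null_effects(animal_sd_av = 0.1), seed = 11,
                       n_per_group = 3)
  tab$amplitude_av[c(2, 9)] <- NA
  fit <- fit_mixed_model(tab, "amplitude_av", "wave")
  expect_identical(fit$n_dropped, 2L)
  expect_identical(nrow(fit$data), nrow(tab) - 2L)
})

test_that("the two-way ANOVA isolates a sex-only weight effect", {
  # identical constants: between-group sums of squares vanish
  const <- data.frame(sex = rep(c("female", "male"), each = 6),
                      genotype = rep(c("B6", "Fmr1", "Fmr1 het"), 4),
                      weight_g = 20)
  an0 <- anova_two_way(const, "weight_g")
  expect_lt(sum(an0$table[["Sum Sq"]][1:3]), 1e-20)

  # the generator's only morphology group effect is female < male weight
  sex_hits <- 0; geno_hits <- 0
  for (s in 1:20) {
    co <- synth_cohort(8, conditions = cohort_conditions(
      itds = 0, frequencies_khz = NULL, clicks = FALSE),
      n_reps = 2, seed = 300 + s)
    an <- anova_two_way(co$animals, "weight_g")
    p <- an$table[["Pr(>F)"]]
    if (p[1] < 0.05) sex_hits <- sex_hits + 1
    if (p[2] < 0.05) geno_hits <- geno_hits + 1
    if (s == 1) {
      expect_true(all(c("sex", "genotype", "sex:genotype") %in%
                        names(an$tukey)))
    }
  }
  expect_gte(sex_hits, 16)   # power >= 0.8
  expect_lte(geno_hits, 4)   # approximate type-I control
})

test_that("null permutations give approximately uniform p-values", {
  set.seed(19)
  base <- data.frame(
    sex = rep(c("female", "male"), each = 12),
    genotype = rep(rep(c("B6", "Fmr1", "Fmr1 het"), each = 4), 2),
    weight_g = rnorm(24, 25, 2))
  pvals <- vapply(1:200, function(i) {
    perm <- base
    # permute genotype labels within sex strata so every cell keeps its size
    for (s in unique(perm$sex)) {
      k <- perm$sex == s
      perm$genotype[k] <- sample(perm$genotype[k])
    }
    anova_two_way(perm, "weight_g")$table[["Pr(>F)"]][2]
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_lt(unname(ks$statistic), 0.15)
})

test_that("degenerate designs are rejected with informative errors", {
  tab <- data.frame(animal = c("a", "b"), sex = c("female", "female"),
                    genotype = c("B6", "B6"), litter = "mixed",
                    wave = "I", amplitude_av = c(1, 2))
  expect_error(fit_mixed_model(tab[, -6], "amplitude_av"), "lacks columns")
  tiny <- data.frame(sex = c("female", "male"), genotype = c("B6", "B6"),
                     weight_g = c(20, 25))
  expect_error(anova_two_way(tiny, "weight_g"), "observations")
})
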