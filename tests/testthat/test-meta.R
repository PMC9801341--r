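# Hand-coded inverse-variance oracle used against both pooling routines.
iv_oracle <- function(md, se, tau2 = 0) {
  w <- 1 / (se^2 + tau2)
  est <- sum(w * md) / sum(w)
  se_p <- sqrt(1 / sum(w))
  c(md = est, se = se_p, lo = est - 1.959964 * se_p,
    hi = est + 1.959964 * se_p)
}

dl_tau2_oracle <- function(md, se) {
  w <- 1 / se^2
  mu <- sum(w * md) / sum(w)
  q <- sum(w * (md - mu)^2)
  df <- length(md) - 1
  max(0, (q - df) / (sum(w) - sum(w^2) / sum(w)))
}

test_that("fixed-effect pooling matches the inverse-variance closed form", {
  one <- fixed_pool(data.frame(study_id = "a", md = 0.2, se = 0.1))
  expect_equal(one$md, 0.2)
  expect_equal(one$se, 0.1)
  expect_equal(one$q, 0)
  expect_equal(one$i2, 0)
  expect_identical(one$k, 1L)

  twin <- fixed_pool(data.frame(study_id = c("a", "b"), md = 0.2, se = 0.1))
  expect_equal(twin$md, 0.2)
  expect_equal(twin$se, 0.1 / sqrt(2))
  expect_equal(twin$q, 0)

  md <- c(0.1, 0.3, 0.2); se <- c(0.1, 0.1, 0.2)
  trio <- fixed_pool(data.frame(study_id = letters[1:3], md = md, se = se))
  want <- iv_oracle(md, se)
  expect_equal(trio$md, want[["md"]])
  expect_equal(trio$ci_low, want[["lo"]])
  expect_equal(trio$ci_high, want[["hi"]])
  expect_equal(trio$tau2, 0)

  expect_error(fixed_pool(data.frame(study_id = character(), md = numeric(),
                                     se = numeric())),
               class = "nutrimpact_domain_error")
})

test_that("DL pooling reduces to fixed effect under homogeneity", {
  hom <- data.frame(study_id = letters[1:3], md = c(0.2, 0.2, 0.2),
                    se = c(0.1, 0.15, 0.2))
  dl <- dl_pool(hom)
  fe <- fixed_pool(hom)
  expect_equal(dl$tau2, 0)
  expect_equal(dl$md, fe$md)
  expect_equal(dl$ci_low, fe$ci_low)

  single <- dl_pool(data.frame(study_id = "a", md = 0.31, se = 0.07))
  expect_equal(single$md, 0.31)
  expect_equal(single$tau2, 0)
})

test_that("heterogeneous studies yield positive tau2 and a wider CI", {
  het <- data.frame(study_id = letters[1:3], md = c(0.0, 0.4, 0.2),
                    se = 0.05)
  dl <- dl_pool(het)
  fe <- fixed_pool(het)
  tau2 <- dl_tau2_oracle(het$md, het$se)
  expect_gt(tau2, 0)
  expect_equal(dl$tau2, tau2)
  want <- iv_oracle(het$md, het$se, tau2)
  expect_equal(dl$md, want[["md"]])
  expect_equal(dl$ci_low, want[["lo"]])
  expect_gt(dl$ci_high - dl$ci_low, fe$ci_high - fe$ci_low)
  expect_gt(dl$i2, 0)
})

test_that("pooling agrees with metafor as an independent implementation", {
  set.seed(42)
  md <- rnorm(8, 0.15, 0.1)
  se <- runif(8, 0.04, 0.2)
  studies <- data.frame(study_id = paste0("s", 1:8), md = md, se = se)

  fe <- fixed_pool(studies)
  ref_fe <- metafor::rma(yi = md, sei = se, method = "FE")
  expect_equal(fe$md, as.numeric(ref_fe$beta), tolerance = 1e-10)
  expect_equal(fe$se, ref_fe$se, tolerance = 1e-10)

  dl <- dl_pool(studies)
  ref_dl <- metafor::rma(yi = md, sei = se, method = "DL")
  expect_equal(dl$md, as.numeric(ref_dl$beta), tolerance = 1e-10)
  expect_equal(dl$se, ref_dl$se, tolerance = 1e-10)
  expect_equal(dl$tau2, ref_dl$tau2, tolerance = 1e-10)
  expect_equal(dl$q, ref_dl$QE, tolerance = 1e-10)
  expect_equal(dl$i2, ref_dl$I2, tolerance = 1e-6)
})

test_that("pooled effects are scale equivariant; Q and I2 are not moved", {
  set.seed(7)
  studies <- data.frame(study_id = paste0("s", 1:6),
                        md = rnorm(6, 0.2, 0.15), se = runif(6, 0.05, 0.2))
  base <- dl_pool(studies)
  scaled <- dl_pool(within(studies, {md <- md * 3; se <- se * 3}))
  expect_equal(scaled$md, base$md * 3)
  expect_equal(scaled$ci_low, base$ci_low * 3)
  expect_equal(scaled$q, base$q)
  expect_equal(scaled$i2, base$i2)
})

test_that("standard errors derive from 95% CIs when absent", {
  s <- study_estimates(data.frame(study_id = "a", md = 0.2,
                                  ci_low = 0.2 - 1.96 * 0.1 ,
                                  ci_high = 0.2 + 1.96 * 0.1))
  expect_equal(s$se, 0.1)
  expect_true(s$se_from_ci)
  expect_error(study_estimates(data.frame(study_id = "a", md = 0.2)),
               class = "nutrimpact_schema_error")
})

test_that("subgroup pooling is independent across food types", {
  mk <- function(ft, md) data.frame(study_id = paste0(ft, 1:4),
                                    food_type = ft, md = md, se = 0.05)
  studies <- rbind(mk("sq_lns", c(0.10, 0.15, 0.2, 0.12)),
                   mk("local_unfortified", c(0.0, -0.05, 0.02, 0.01)))
  by_type <- subgroup_pool(studies)
  expect_named(by_type, c("sq_lns", "local_unfortified"))
  expect_equal(by_type$sq_lns$md,
               dl_pool(studies[studies$food_type == "sq_lns", ])$md)

  # perturbing one subgroup leaves the other untouched
  studies2 <- studies
  studies2$md[studies2$food_type == "local_unfortified"] <- c(0.5, 0.6, 0.4, 0.55)
  by_type2 <- subgroup_pool(studies2)
  expect_equal(by_type2$sq_lns$md, by_type$sq_lns$md)

  unlabelled <- studies
  unlabelled$food_type[1] <- NA
  expect_error(subgroup_pool(unlabelled), class = "nutrimpact_domain_error")
})

test_that("a trial table reads from delimited text", {
  path <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(study_id = c("t1", "t2"), food_type = "sq_lns",
                   outcome = "haz_md", md = c(0.1, 0.2),
                   ci_low = c(-0.1, 0.0), ci_high = c(0.3, 0.4),
                   n_int = 500L, n_ctl = 500L)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  trials <- read_trials(path)
  expect_identical(nrow(trials), 2L)
  expect_equal(trials$se, c(0.4, 0.4) / (2 * 1.96))
})
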