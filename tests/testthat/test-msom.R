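test_that("state enumeration is canonical and exhaustive", {
  expect_equal(unname(enumerate_states(1)), matrix(c(0L, 1L), 2, 1))
  expect_equal(unname(enumerate_states(2)),
               matrix(as.integer(c(0, 1, 0, 1, 0, 0, 1, 1)), 4, 2))
  s3 <- enumerate_states(3)
  expect_equal(nrow(unique(s3)), 8)
  expect_identical(enumerate_states(3), s3)  # stable across calls
  expect_error(enumerate_states(0))
  expect_error(enumerate_states(5))
})

test_that("state probabilities match the two-guild enumeration oracle", {
  # symmetric case: all f zero
  f0 <- natural_params(c(a = 0, b = 0), c("a:b" = 0))
  expect_equal(state_probabilities(f0)$probability, rep(0.25, 4))
  # no interaction factorises into independent marginals
  f <- natural_params(c(a = 0.7, b = -1.2), c("a:b" = 0))
  p <- state_probabilities(f)$probability
  psi_a <- p[2] + p[4]; psi_b <- p[3] + p[4]
  expect_equal(p[4], psi_a * psi_b, tolerance = 1e-12)
  # worked interaction case against the oracle
  f <- natural_params(c(a = 0.5, b = -0.3), c("a:b" = 1.0))
  expect_equal(state_probabilities(f)$probability,
               oracle_state_probs2(0.5, -0.3, 1.0), tolerance = 1e-12)
  expect_equal(state_probabilities(f)$probability[4], 0.4949, tolerance = 2e-4)
  expect_error(natural_params(c(a = Inf, b = 0)))
})

test_that("state probabilities sum to one across random parameters", {
  set.seed(99)
  for (i in 1:1000) {
    S <- sample(2:3, 1)
    g <- letters[1:S]
    f <- natural_params(stats::setNames(runif(S, -5, 5), g),
                        stats::setNames(runif(S * (S - 1) / 2, -5, 5), camshield:::pair_names(g)))
    expect_equal(sum(state_probabilities(f)$probability), 1, tolerance = 1e-12)
  }
})

test_that("site likelihood matches closed forms for one guild", {
  # psi = 0.5, p = 0.5, K = 1, y = 0: 0.5*0.5 + 0.5*1
  dist <- c(0.5, 0.5)
  expect_equal(site_likelihood(0, 1, 0.5, dist), 0.75)
  # K = 2, history (1,0): only the occupied state contributes
  expect_equal(site_likelihood(1, 2, 0.5, dist), 0.5 * 0.5 * 0.5)
  expect_error(site_likelihood(1, 0, 0.5, dist))
})

test_that("site likelihood equals exhaustive enumeration for all small histories", {
  set.seed(3)
  for (S in 2:3) {
    g <- letters[1:S]
    f <- natural_params(stats::setNames(runif(S, -1, 1), g),
                        stats::setNames(runif(S * (S - 1) / 2, -1, 1),
                                        camshield:::pair_names(g)))
    pz <- state_probabilities(f)$probability
    p <- runif(S, 0.2, 0.8)
    for (K in 1:3) {
      hist_space <- expand.grid(rep(list(0:1), S * K))
      for (r in seq_len(nrow(hist_space))) {
        hs <- lapply(seq_len(S), function(s)
          as.numeric(hist_space[r, ((s - 1) * K + 1):(s * K)]))
        y <- vapply(hs, sum, numeric(1))
        expect_equal(site_likelihood(y, K, p, pz),
                     oracle_site_likelihood(hs, p, pz), tolerance = 1e-12)
      }
    }
  }
})

test_that("fit recovers parameters and reports a valid AIC / vcov", {
  f_true <- natural_params(c(prey = 0.6, human = -0.4), c("prey:human" = 1.2))
  p_true <- c(prey = 0.4, human = 0.4)
  h <- simulate_histories(f_true, p_true, 300, 20, seed = 5)
  fit <- fit_msom(h, interaction_order = 2, seed = 1)
  expect_equal(fit$aic, 2 * fit$n_params - 2 * fit$loglik, tolerance = 1e-9)
  expect_equal(fit$n_params, 5)
  expect_true(isSymmetric(fit$vcov, tol = 1e-8))
  expect_true(all(eigen(fit$vcov, only.values = TRUE)$values > -1e-8))
  truth <- c(0.6, -0.4, 1.2, qlogis(0.4), qlogis(0.4))
  se <- sqrt(diag(fit$vcov))
  expect_true(all(abs(fit$estimates - truth) < 3.5 * se))
  # loglik at the MLE is at least the loglik at the truth (MLE optimality)
  st <- camshield:::history_stats(lapply(h, function(m) {
    storage.mode(m) <- "integer"; m
  }))
  ll_truth <- -camshield:::msom_negloglik(truth, st, c("prey", "human"), 2,
                                          enumerate_states(2))
  expect_gte(fit$loglik, ll_truth - 1e-6)
})

test_that("first-order fit has no interaction terms and 2S + S parameters", {
  f_true <- natural_params(c(a = 0.3, b = 0.1), c("a:b" = 0))
  h <- simulate_histories(f_true, c(a = 0.5, b = 0.5), 150, 10, seed = 2)
  fit <- fit_msom(h, interaction_order = 1, seed = 1)
  expect_equal(fit$n_params, 4)
  expect_null(fit$params$second_order)
  expect_equal(sort(names(fit$estimates)),
               sort(c("f[a]", "f[b]", "logit_p[a]", "logit_p[b]")))
})

test_that("duplicating every site doubles the log-likelihood", {
  f_true <- natural_params(c(a = 0.4, b = -0.2), c("a:b" = 0.8))
  h <- simulate_histories(f_true, c(a = 0.45, b = 0.35), 120, 8, seed = 9)
  h2 <- lapply(h, function(m) rbind(m, m))
  fit1 <- fit_msom(h, seed = 1)
  fit2 <- fit_msom(h2, seed = 1)
  expect_equal(fit2$loglik, 2 * fit1$loglik, tolerance = 1e-4)
  expect_equal(fit2$estimates, fit1$estimates, tolerance = 1e-3)
})

test_that("model comparison ranks by AIC with ties broken by parsimony", {
  fit_a <- structure(list(spec = list(n_sites = 10, n_occasions = 5,
                                      guild_names = c("a", "b"), interaction_order = 1),
                          loglik = -100, aic = 2 * 6 + 200, n_params = 6),
                     class = "msom_fit")
  fit_b <- structure(list(spec = list(n_sites = 10, n_occasions = 5,
                                      guild_names = c("a", "b"), interaction_order = 2),
                          loglik = -100, aic = 2 * 9 + 200, n_params = 9),
                     class = "msom_fit")
  cmp <- compare_models(small = fit_a, large = fit_b)
  expect_equal(cmp$model, c("small", "large"))
  expect_equal(cmp$delta_aic, c(0, 6))
  expect_true(cmp$best[1])
  one <- compare_models(only = fit_a)
  expect_equal(nrow(one), 1)
  expect_equal(one$delta_aic, 0)
  fit_c <- fit_a; fit_c$spec$n_sites <- 11
  expect_error(compare_models(fit_a, fit_c), "different dimensions")
})

test_that("derived occupancy quantities match the enumeration oracle", {
  f_true <- natural_params(c(a = 0.5, b = -0.3), c("a:b" = 1.0))
  h <- simulate_histories(f_true, c(a = 0.5, b = 0.5), 400, 15, seed = 21)
  fit <- fit_msom(h, seed = 1)
  # overwrite estimates with the oracle parameter point to test the algebra
  fit$estimates[1:3] <- c(0.5, -0.3, 1.0)
  pz <- oracle_state_probs2(0.5, -0.3, 1.0)
  m <- marginal_occupancy(fit, "a")
  expect_equal(m$estimate, pz[2] + pz[4], tolerance = 1e-12)
  expect_equal(m$estimate, 0.7406, tolerance = 1e-4)
  co <- cooccurrence_probability(fit, "a", "b")
  expect_equal(co$estimate, pz[4], tolerance = 1e-12)
  cnd <- conditional_occupancy(fit, "a", "b", present = TRUE)
  expect_equal(cnd$estimate, pz[4] / (pz[3] + pz[4]), tolerance = 1e-12)
  expect_equal(cnd$estimate, 0.8176, tolerance = 1e-4)
  expect_true(m$ci_low >= 0 && m$ci_high <= 1 && m$ci_low <= m$ci_high)
})

test_that("symmetric parameters give the symmetric probabilities", {
  f0 <- natural_params(c(a = 0, b = 0), c("a:b" = 0))
  h <- simulate_histories(f0, c(a = 0.5, b = 0.5), 100, 10, seed = 4)
  fit <- fit_msom(h, seed = 1)
  fit$estimates[1:3] <- 0
  expect_equal(marginal_occupancy(fit, "a")$estimate, 0.5, tolerance = 1e-12)
  expect_equal(cooccurrence_probability(fit, "a", "b")$estimate, 0.25, tolerance = 1e-12)
  # independence: conditional equals marginal when the pair term is zero
  expect_equal(conditional_occupancy(fit, "a", "b", TRUE)$estimate,
               marginal_occupancy(fit, "a")$estimate, tolerance = 1e-12)
})

test_that("conditional contrast sign follows the interaction sign", {
  f_base <- c(a = 0.2, b = -0.1)
  h <- simulate_histories(natural_params(f_base, c("a:b" = 0)),
                          c(a = 0.5, b = 0.5), 100, 10, seed = 6)
  fit <- fit_msom(h, seed = 1)
  for (f12 in c(-2, -0.5, 0.5, 2)) {
    fit$estimates[1:3] <- c(f_base, f12)
    d <- conditional_occupancy(fit, "a", "b", TRUE)$estimate -
      conditional_occupancy(fit, "a", "b", FALSE)$estimate
    expect_equal(sign(d), sign(f12))
  }
  # strong positive interaction: co-occurrence approaches the marginal
  fit$estimates[1:3] <- c(f_base, 20)
  expect_equal(cooccurrence_probability(fit, "a", "b")$estimate,
               marginal_occupancy(fit, "a")$estimate, tolerance = 1e-6)
})

test_that("marginal occupancy is monotone in the guild's own f", {
  f0 <- natural_params(c(a = 0, b = 0), c("a:b" = 0.5))
  h <- simulate_histories(f0, c(a = 0.5, b = 0.5), 100, 10, seed = 8)
  fit <- fit_msom(h, seed = 1)
  vals <- vapply(seq(-2, 2, 0.5), function(fa) {
    fit$estimates[1:3] <- c(fa, 0.3, 0.5)
    marginal_occupancy(fit, "a")$estimate
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("normal-resampling intervals agree broadly with delta-method intervals", {
  f_true <- natural_params(c(a = 0.5, b = -0.3), c("a:b" = 1.0))
  h <- simulate_histories(f_true, c(a = 0.5, b = 0.4), 300, 15, seed = 13)
  fit <- fit_msom(h, seed = 1)
  d <- marginal_occupancy(fit, "a", method = "delta")
  b <- marginal_occupancy(fit, "a", method = "boot", B = 2000, seed = 2)
  expect_equal(d$estimate, b$estimate)
  expect_lt(abs(d$ci_low - b$ci_low), 0.05)
  expect_lt(abs(d$ci_high - b$ci_high), 0.05)
  # resampling is deterministic under a fixed seed
  b2 <- marginal_occupancy(fit, "a", method = "boot", B = 2000, seed = 2)
  expect_identical(b, b2)
})

test_that("tidy and glance expose the fit in broom form", {
  f_true <- natural_params(c(a = 0.3, b = 0.2), c("a:b" = 0.4))
  h <- simulate_histories(f_true, c(a = 0.5, b = 0.5), 80, 8, seed = 30)
  fit <- fit_msom(h, seed = 1)
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std.error", "statistic", "p.value"))
  expect_equal(nrow(td), 5)
  gl <- glance(fit)
  expect_equal(gl$AIC, fit$aic)
  expect_true(gl$converged)
})

test_that("a guild with zero detections triggers a warning", {
  h <- list(a = matrix(rbinom(200, 1, 0.3), 20),
            b = matrix(0L, 20, 10))
  expect_warning(fit_msom(h, interaction_order = 1, seed = 1), "zero detections")
})
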