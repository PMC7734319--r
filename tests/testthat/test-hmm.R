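test_that("emission binning follows the seven-interval construction", {
  b <- emission_binning(0.2, 0.06, 0.62, 0.05)
  expect_equal(b$delta_p2, (0.62 - 0.2) / 7, tolerance = 1e-15)
  expect_equal(b$edges, 0.2 + (0:7) * (0.62 - 0.2) / 7, tolerance = 1e-15)
  expect_error(emission_binning(0.6, 0.05, 0.2, 0.05), "mu_L < mu_O")
})

test_that("symbol assignment: extremes, interior bins and tie-breaking", {
  # binary-exact binning (delta = 0.125) so edge ties are unambiguous
  b <- emission_binning(0.25, 0.05, 0.25 + 7 * 0.125, 0.05)
  d <- b$delta_p2
  expect_identical(d, 0.125)
  x <- c(0.1, 1.2, 0.25 + 0.5 * d, 0.25 + 6.5 * d,
         0.25,                # exactly mu_L: lowest interior bin
         0.25 + d,            # exactly first interior edge: tie down
         0.25 + 7 * d)        # exactly mu_O: symbol 7, not 8
  s <- bin_emissions(x, b)
  expect_equal(s, c(0L, 8L, 1L, 7L, 1L, 1L, 7L))
  m <- matrix(x[1:6], 2, 3)
  sm <- bin_emissions(m, b)
  expect_equal(dim(sm), c(2L, 3L))
  expect_equal(as.vector(sm), c(0L, 8L, 1L, 7L, 1L, 1L))
})

test_that("initialization formulas match hand evaluation to 1e-12", {
  mu_L <- 0.21; s_L <- 0.07; mu_O <- 0.64; s_O <- 0.045
  b <- emission_binning(mu_L, s_L, mu_O, s_O)
  m <- init_hmm(b)
  mu_I_hand <- (s_L * mu_O + s_O * mu_L) / (s_O + s_L)
  sigma_I_hand <- min(abs(mu_O - mu_I_hand), abs(mu_L - mu_I_hand)) / 3
  expect_equal(m$mu_I, mu_I_hand, tolerance = 1e-12)
  expect_equal(m$sigma_I, sigma_I_hand, tolerance = 1e-12)
  # emission rows are normal integrals over the bins, renormalized
  breaks <- c(-Inf, b$edges, Inf)
  for (row in list(c("D", mu_L, s_L), c("I", mu_I_hand, sigma_I_hand),
                   c("O", mu_O, s_O))) {
    p <- diff(pnorm(breaks, as.numeric(row[2]), as.numeric(row[3])))
    expect_equal(unname(m$emit[row[1], ]), p / sum(p), tolerance = 1e-12)
  }
  expect_equal(rowSums(m$emit), c(D = 1, I = 1, O = 1), tolerance = 1e-10)
  expect_equal(rowSums(m$trans), c(D = 1, I = 1, O = 1), tolerance = 1e-10)
  expect_equal(unname(diag(m$trans)), rep(0.98, 3))
})

test_that("Viterbi equals exhaustive enumeration on 100 random models", {
  set.seed(2024)
  for (rep in 1:100) {
    m <- rand_hmm()
    obs <- sample(0:8, 8, replace = TRUE)
    got <- cpp_viterbi(as.integer(obs), m$start, m$trans, m$emit)
    oracle <- enum_hmm(obs, m)
    expect_equal(enum_path_logp(obs, got + 1L, m), oracle$logp,
                 tolerance = 1e-10)
    expect_equal(as.integer(got + 1L), oracle$path)
    ll <- cpp_forward_loglik(as.integer(obs), m$start, m$trans, m$emit)
    expect_equal(ll, oracle$total_loglik, tolerance = 1e-10)
  }
})

test_that("Baum-Welch log-likelihood is non-decreasing and converges", {
  set.seed(7)
  b <- emission_binning(0.15, 0.05, 0.55, 0.05)
  m0 <- init_hmm(b)
  spec <- synthetic_spec(seed = 7, n_frames = 400, n_lipids_per_leaflet = 15)
  ss <- gen_state_sequences(spec, binning = b, n_lipids = 30)
  m <- train_hmm(m0, ss$symbols)
  tr <- m$log_likelihood_trace
  expect_gt(length(tr), 1)
  expect_true(all(diff(tr) >= -1e-8 * abs(tr[-length(tr)])))
  expect_true(m$trained)
  # relabeling puts states in D < I < O emission order
  wm <- as.vector(m$emit %*% 0:8)
  expect_true(all(diff(wm) > 0))
  # rows remain stochastic after training
  expect_equal(unname(rowSums(m$trans)), rep(1, 3), tolerance = 1e-10)
  expect_equal(unname(rowSums(m$emit)), rep(1, 3), tolerance = 1e-10)
})

test_that("decode_states and path_loglik are consistent", {
  set.seed(9)
  m <- rand_hmm()
  b <- emission_binning(0.15, 0.05, 0.55, 0.05)
  model <- init_hmm(b)
  model$start_prob[] <- m$start
  model$trans[] <- m$trans
  model$emit[] <- m$emit
  model$trained <- TRUE
  obs <- matrix(sample(0:8, 40, replace = TRUE), 20, 2)
  dec <- decode_states(model, obs, lipid_ids = c(7L, 9L))
  expect_s3_class(dec, "state_trajectory")
  expect_equal(dim(dec$states), c(20L, 2L))
  expect_true(all(dec$states %in% c("D", "I", "O")))
  # the Viterbi path is at least as likely as simple alternatives
  for (j in 1:2) {
    v_lp <- path_loglik(model, obs[, j], dec$states[, j])
    for (alt in list(rep("D", 20), rep("O", 20),
                     sample(c("D", "I", "O"), 20, replace = TRUE)))
      expect_gte(v_lp, path_loglik(model, obs[, j], alt))
  }
})

test_that("stationary distribution solves pi = pi P", {
  set.seed(11)
  m <- rand_hmm()
  dimnames(m$trans) <- list(c("D", "I", "O"), c("D", "I", "O"))
  pi_hat <- stationary_distribution(m$trans)
  expect_equal(sum(pi_hat), 1, tolerance = 1e-12)
  expect_equal(as.vector(pi_hat %*% m$trans), unname(pi_hat),
               tolerance = 1e-12)
})

test_that("unimodal pooled P2 triggers the overlap warning", {
  set.seed(13)
  x <- rnorm(2000, 0.3, 0.05)
  expect_warning(fit_emission_gmm(x), "unimodal|overlap")
  expect_error(fit_emission_gmm(rnorm(50, 0.3, 0.05)), "200")
})

test_that("domain fractions: composition rows sum to 100", {
  out <- small_fixture()
  lf <- assign_leaflets(out$view)
  p2 <- compute_p2(out$view, lf)
  cls <- hmm_classify(p2)
  fr <- domain_fractions(cls$states)
  for (st in c("D", "I", "O")) {
    rows <- fr$composition[fr$composition$state == st, ]
    expect_equal(sum(rows$percent), 100, tolerance = 1e-9)
  }
  expect_equal(sum(fr$distribution$percent), 100, tolerance = 1e-9)
  expect_true(all(fr$distribution$se >= 0))
})

test_that("reference-model decoding reuses frozen parameters", {
  out <- small_fixture()
  lf <- assign_leaflets(out$view)
  p2 <- compute_p2(out$view, lf)
  cls <- hmm_classify(p2)
  again <- hmm_classify(p2, reference = cls$models)
  expect_identical(cls$states$states, again$states$states)
})

test_that("dwell lifetimes: censoring, weighting and fit refusal", {
  # hand-built state matrix: lipid 1 = D(5) O(3) D(4); lipid 2 = O(12)
  st <- matrix("O", 12, 2)
  st[1:5, 1] <- "D"; st[9:12, 1] <- "D"
  traj <- structure(list(states = st, lipid_ids = 1:2,
                         lipid_type = c("POPC", "POPC"),
                         times = (0:11) * 1000),
                    class = "state_trajectory")
  d <- dwell_lifetimes(traj, "D")
  # both D dwells touch a trajectory end: censored, no uncensored dwells
  expect_true(all(d$dwells$censored))
  expect_true(is.na(d$fit_tau1))
  o <- dwell_lifetimes(traj, "O")
  # lipid 1's O dwell (3 frames) is interior; lipid 2's spans everything
  expect_equal(sum(!o$dwells$censored), 1L)
  expect_equal(o$dwells$length_ns[!o$dwells$censored], 3)
})
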