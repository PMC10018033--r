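test_that("lppd reduces to the log-likelihood for a single draw", {
  tab <- tiny_trials()
  bound <- bind_model(build_model("pse_slope"), tab)
  set.seed(14)
  th <- init_params_for_test(bound)
  arr <- constant_draws(bound, th, n_iter = 1, n_chains = 1)
  fit <- fake_fit(bound, arr)
  expect_equal(lppd(fit)$value, log_likelihood(bound, th, tab))
})

test_that("lppd averages the likelihood across draws", {
  # one cell y=1, n=1; two draws with success probabilities 0.3 and 0.7
  one <- psy_trials(tibble::tibble(subject = "s1", stimulus = 0,
                                   condition = "c0", successes = 1L,
                                   trials = 1L))
  bound <- bind_model(build_model("pse_slope"), one)
  th <- setNames(rep(1, length(bound$param_names)), bound$param_names)
  arr <- constant_draws(bound, th, n_iter = 2, n_chains = 1)
  arr[, , "beta[subject=s1,cond=c0]"] <- 1
  # pnorm(-pse) = 0.3 and 0.7
  arr[, , "pse[subject=s1,cond=c0]"] <- c(-qnorm(0.3), -qnorm(0.7))
  fit <- fake_fit(bound, arr)
  expect_equal(lppd(fit)$value, log(0.5))
})

test_that("lppd matches a brute-force double loop over cells and draws", {
  tab <- tiny_trials()
  bound <- bind_model(build_model("pse_slope"), tab)
  set.seed(15)
  n_iter <- 5
  n_chains <- 2
  arr <- array(rnorm(n_iter * n_chains * length(bound$param_names), 1, 0.3),
               dim = c(n_iter, n_chains, length(bound$param_names)),
               dimnames = list(NULL, NULL, bound$param_names))
  fit <- fake_fit(bound, arr)
  res <- lppd(fit)

  agg <- aggregate_binomial(tab)
  total <- 0
  for (r in seq_len(nrow(agg))) {
    probs <- numeric(0)
    for (ch in seq_len(n_chains)) {
      for (s in seq_len(n_iter)) {
        pse <- arr[s, ch, sprintf("pse[subject=%s,cond=c0]", agg$subject[r])]
        bet <- arr[s, ch, sprintf("beta[subject=%s,cond=c0]", agg$subject[r])]
        probs <- c(probs, dbinom(agg$successes[r], agg$trials[r],
                                 pnorm(bet * (agg$stimulus[r] - pse))))
      }
    }
    total <- total + log(mean(probs))
  }
  expect_equal(res$value, total)
  # per-chain mc error oracle
  per_chain <- sapply(seq_len(n_chains), function(ch) {
    tot <- 0
    for (r in seq_len(nrow(agg))) {
      probs <- sapply(seq_len(n_iter), function(s) {
        pse <- arr[s, ch, sprintf("pse[subject=%s,cond=c0]", agg$subject[r])]
        bet <- arr[s, ch, sprintf("beta[subject=%s,cond=c0]", agg$subject[r])]
        dbinom(agg$successes[r], agg$trials[r],
               pnorm(bet * (agg$stimulus[r] - pse)))
      })
      tot <- tot + log(mean(probs))
    }
    tot
  })
  expect_equal(res$mc_error, sd(per_chain))
})

test_that("lppd converges to the quadrature value on a conjugate-style toy", {
  # one subject, beta fixed at 1, pse drawn iid from N(2, 0.4^2): the exact
  # predictive density is a 1-d integral evaluated by quadrature
  tab <- psy_trials(tibble::tibble(subject = "s1", stimulus = c(1, 2, 3),
                                   condition = "c0",
                                   successes = c(2L, 5L, 8L), trials = 10L))
  bound <- bind_model(build_model("pse_slope"), tab)
  truth <- sum(sapply(seq_len(nrow(tab)), function(r) {
    log(integrate(function(p) {
      dbinom(tab$successes[r], tab$trials[r],
             pnorm(tab$stimulus[r] - p)) * dnorm(p, 2, 0.4)
    }, -Inf, Inf, rel.tol = 1e-10)$value)
  }))
  mean_abs_err <- sapply(c(100, 10000), function(S) {
    errs <- sapply(1:8, function(rep) {
      set.seed(33 + rep)
      arr <- constant_draws(bound, setNames(rep(1, length(bound$param_names)),
                                            bound$param_names),
                            n_iter = S, n_chains = 1)
      arr[, , "pse[subject=s1,cond=c0]"] <- rnorm(S, 2, 0.4)
      abs(lppd(fake_fit(bound, arr))$value - truth)
    })
    mean(errs)
  })
  expect_lt(mean_abs_err[2], mean_abs_err[1])
  expect_lt(mean_abs_err[2], 0.02)
})

test_that("sum of squared errors matches closed cases and an oracle", {
  # observed 0.5, fitted 0.25 -> 0.0625
  one <- psy_trials(tibble::tibble(subject = "s1", stimulus = 0,
                                   condition = "c0", successes = 2L,
                                   trials = 4L))
  bound <- bind_model(build_model("pse_slope"), one)
  th <- setNames(rep(1, length(bound$param_names)), bound$param_names)
  th["beta[subject=s1,cond=c0]"] <- 1
  th["pse[subject=s1,cond=c0]"] <- -qnorm(0.25)   # pnorm(-pse) = 0.25
  fit <- fake_fit(bound, constant_draws(bound, th))
  expect_equal(sum_squared_errors(fit, "individual"), 0.0625)

  # fitted equal to observed -> 0
  th0 <- th
  th0["pse[subject=s1,cond=c0]"] <- 0   # pnorm(0) = 0.5 = 2/4
  expect_equal(sum_squared_errors(fake_fit(bound, constant_draws(bound, th0)),
                                  "individual"), 0)

  # brute-force oracle on a two-subject table, both levels
  tab <- tiny_trials()
  b2 <- bind_model(build_model("pse_slope"), tab)
  set.seed(19)
  arr <- array(rnorm(20 * 2 * length(b2$param_names), 1, 0.2),
               dim = c(20, 2, length(b2$param_names)),
               dimnames = list(NULL, NULL, b2$param_names))
  fit2 <- fake_fit(b2, arr)
  means <- apply(arr, 3, mean)
  for (lvl in c("individual", "overall")) {
    oracle <- 0
    for (r in seq_len(nrow(tab))) {
      if (lvl == "individual") {
        pse <- means[sprintf("pse[subject=%s,cond=c0]", tab$subject[r])]
        bet <- means[sprintf("beta[subject=%s,cond=c0]", tab$subject[r])]
      } else {
        pse <- means["PSE[cond=c0]"]
        bet <- means["b[cond=c0]"]
      }
      oracle <- oracle +
        (tab$successes[r] / tab$trials[r] -
           pnorm(bet * (tab$stimulus[r] - pse)))^2
    }
    expect_equal(sum_squared_errors(fit2, lvl), unname(oracle))
  }
})

test_that("individual-level SSE beats overall-level SSE on heterogeneous data", {
  # subjects differ (non-degenerate between-subject variance), so subject-level
  # posterior means should fit better than the population means, on average
  sses <- sapply(1:5, function(rep) {
    tr <- tibble::tibble(group = "all", condition = "c0", pse = 2.5,
                         beta = 0.8, tau_pse = 1, tau_beta = 16)
    des <- design_spec(6, c(0.5, 1.5, 2.5, 3.5, 4.5), 10,
                       conditions = "c0")
    dat <- simulate_study(des, tr, seed = 100 + rep)$data
    fit <- run_chains(dat, build_model("pse_slope"),
                      quick_config(seed = rep, n_iter = 250, n_warmup = 250))
    c(sum_squared_errors(fit, "individual"),
      sum_squared_errors(fit, "overall"))
  })
  expect_lt(mean(sses[1, ]), mean(sses[2, ]))
})

test_that("posterior overlap follows the histogram-intersection contract", {
  set.seed(3)
  x <- rnorm(5000)
  expect_equal(posterior_overlap(x, x), 1)
  expect_equal(posterior_overlap(runif(1000), runif(1000, 10, 11)), 0)
  y <- rnorm(5000, 0.8)
  expect_equal(posterior_overlap(x, y), posterior_overlap(y, x))
  o <- posterior_overlap(x, y)
  expect_gt(o, 0)
  expect_lt(o, 1)
  # insensitive-enough to binning to be a usable statistic
  expect_equal(posterior_overlap(x, y, n_bins = 40),
               posterior_overlap(x, y, n_bins = 60), tolerance = 0.05)
  expect_error(posterior_overlap(x, y, n_bins = 1), "n_bins")
})

test_that("compare_models emits the documented schema and deterministic rows", {
  tab <- tiny_trials()
  bound <- bind_model(build_model("pse_slope"), tab)
  set.seed(25)
  th <- init_params_for_test(bound)
  fit <- fake_fit(bound, constant_draws(bound, th))
  out <- compare_models(list(m1 = fit, m2 = fit))
  expect_identical(names(out),
                   c("model", "effects", "loglik", "lppd", "lppd_mc_error",
                     "sse", "pse_ci_low", "pse_ci_high", "ci_width"))
  expect_equal(nrow(out), 4)
  expect_identical(out$effects, rep(c("individual", "overall"), 2))
  # identical fits -> identical rows
  expect_equal(out[1:2, -1], out[3:4, -1])
  # constant draws: lppd equals the log-likelihood at that point, CI width 0
  ind <- out[out$model == "m1" & out$effects == "individual", ]
  expect_equal(ind$lppd, log_likelihood(bound, th, tab))
  expect_equal(out$ci_width[2], 0)
})

test_that("select_a0 picks the minimum width with ties toward more borrowing", {
  expect_equal(select_a0(c(`0` = 0.05, `0.5` = 0.04, `1` = 0.07)), 0.5)
  expect_equal(select_a0(c(`0` = 0.05, `0.5` = 0.05, `1` = 0.05)), 1)
  expect_equal(select_a0(c(`0` = 0.3, `0.5` = 0.2, `1` = 0.1)), 1)
  expect_equal(select_a0(c(`0` = 0.3)), 0)
  expect_error(select_a0(numeric(0)), "empty")
})
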