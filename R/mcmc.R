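#' MCMC chain configuration
#'
#' @param n_chains Number of chains (at least 2, so that R-hat is defined).
#' @param n_iter Post-warmup iterations kept per chain (after thinning).
#' @param n_warmup Warmup (adaptation) iterations, discarded.
#' @param thin Thinning interval (keep every `thin`-th post-warmup state).
#' @param seed Master seed; per-chain seeds are `seed + chain - 1`.
#' @param step0 Initial random-walk step size for subject-level updates
#'   (adapted during warmup toward a 44% acceptance rate).
#' @return A list of class `chain_config`.
#' @export
chain_config <- function(n_chains = 4, n_iter = 5000, n_warmup = 5000,
                         thin = 1, seed = 1, step0 = 0.5) {
  if (n_chains < 2) {
    stop("n_chains must be >= 2 (required for the R-hat diagnostic)",
         call. = FALSE)
  }
  stopifnot(n_iter >= 1, n_warmup >= 0, thin >= 1, step0 > 0)
  structure(list(n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
                 n_warmup = as.integer(n_warmup), thin = as.integer(thin),
                 seed = as.integer(seed), step0 = step0),
            class = "chain_config")
}

# ---- sampler internals -----------------------------------------------------

# Precompute conjugate-update index structures for a bound model.
engine_plan <- function(bound) {
  blocks <- bound$blocks
  pop <- bound$pop
  # population nodes: subject-level children (either slot) + pop children
  pop_children <- lapply(seq_len(nrow(pop)), function(j) {
    id <- pop$idx[j]
    r1 <- which(blocks$pop1 == id)
    r2 <- which(blocks$pop2 == id)
    kids <- rbind(
      data.frame(idx = blocks$i1[r1], coef = blocks$coef1[r1],
                 tau = blocks$tau1[r1]),
      data.frame(idx = blocks$i2[r2], coef = blocks$coef2[r2],
                 tau = blocks$tau2[r2]))
    pk <- which(!is.na(pop$parent_idx) & pop$parent_idx == id)
    cell_rows <- which(bound$cells$block %in% c(r1, r2))
    list(idx = kids$idx, coef = kids$coef, tau = kids$tau,
         pop_idx = pop$idx[pk], pop_coef = pop$coef[pk],
         pop_sigma = pop$sigma_idx[pk], cells = cell_rows)
  })
  # tau nodes: flat member table (node row, param idx, its pop idx, coef)
  tau_members <- rbind(
    data.frame(node = match(blocks$tau1, bound$tau$idx), idx = blocks$i1,
               pop = blocks$pop1, coef = blocks$coef1),
    data.frame(node = match(blocks$tau2, bound$tau$idx), idx = blocks$i2,
               pop = blocks$pop2, coef = blocks$coef2))
  tau_members <- tau_members[order(tau_members$node), ]
  tau_counts <- as.vector(table(factor(tau_members$node,
                                       levels = seq_len(nrow(bound$tau)))))
  # sigma nodes
  has_parent <- !is.na(pop$parent_idx)
  sigma_members <- data.frame(node = match(pop$sigma_idx, bound$sigma$idx),
                              idx = pop$idx, parent = pop$parent_idx,
                              coef = pop$coef, has_parent = has_parent)
  sigma_members <- sigma_members[order(sigma_members$node), ]
  sigma_counts <- as.vector(table(factor(sigma_members$node,
                                         levels = seq_len(nrow(bound$sigma)))))
  # per tau node: member params and the data cells their blocks own, for the
  # joint (deviations, precision) scale move
  tau_scale <- lapply(seq_len(nrow(bound$tau)), function(k) {
    mem <- tau_members[tau_members$node == k, ]
    blk1 <- which(blocks$tau1 == bound$tau$idx[k])
    blk2 <- which(blocks$tau2 == bound$tau$idx[k])
    cell_rows <- which(bound$cells$block %in% c(blk1, blk2))
    list(idx = mem$idx, pop = mem$pop, coef = mem$coef, cells = cell_rows)
  })
  list(pop_children = pop_children, tau_members = tau_members,
       tau_counts = tau_counts, sigma_members = sigma_members,
       sigma_counts = sigma_counts, tau_scale = tau_scale)
}

# Draw an initial state from the hyperpriors (precision draws that would
# overflow are replaced by their prior means).
init_from_prior <- function(bound) {
  hp <- bound$spec$hyperpriors
  theta <- numeric(length(bound$param_names))
  names(theta) <- bound$param_names
  safe_gamma <- function(n, shape, rate) {
    v <- stats::rgamma(n, shape = shape, rate = rate)
    bad <- v < 1e-12 | v > 1e12 | !is.finite(v)
    prior_mean <- rep_len(shape / rate, n)
    v[bad] <- prior_mean[bad]
    v
  }
  theta[bound$sigma$idx] <- safe_gamma(nrow(bound$sigma), bound$sigma$shape,
                                       bound$sigma$rate)
  for (j in seq_len(nrow(bound$pop))) {      # parents precede children
    m0 <- if (is.na(bound$pop$parent_idx[j])) hp$pop_mean else
      bound$pop$coef[j] * theta[bound$pop$parent_idx[j]]
    theta[bound$pop$idx[j]] <- stats::rnorm(
      1, m0, 1 / sqrt(theta[bound$pop$sigma_idx[j]]))
  }
  theta[bound$tau$idx] <- safe_gamma(nrow(bound$tau), bound$tau$shape,
                                     bound$tau$rate)
  b <- bound$blocks
  theta[b$i1] <- stats::rnorm(nrow(b), b$coef1 * theta[b$pop1],
                              1 / sqrt(theta[b$tau1]))
  theta[b$i2] <- stats::rnorm(nrow(b), b$coef2 * theta[b$pop2],
                              1 / sqrt(theta[b$tau2]))
  theta
}

# One chain of the Metropolis-within-Gibbs sampler. Returns a matrix of kept
# draws [n_iter x P].
run_one_chain <- function(bound, plan, config, chain_seed, init = NULL) {
  set.seed(chain_seed)
  theta <- if (is.null(init)) init_from_prior(bound) else {
    stopifnot(all(bound$param_names %in% names(init)))
    init[bound$param_names]
  }
  cells <- bound$cells
  blocks <- bound$blocks
  B <- bound$n_blocks
  P <- length(theta)
  par_kind <- bound$parameterization
  n_keep <- config$n_iter
  n_total <- config$n_warmup + n_keep * config$thin

  ll_cells <- cell_loglik(par_kind, theta[cells$i1], theta[cells$i2],
                          cells$x, cells$y, cells$n, cells$lch)
  ls1 <- rep(log(config$step0), B)
  ls2 <- rep(log(config$step0), B)
  n_pop <- nrow(bound$pop)
  ls_pop <- rep(log(config$step0), n_pop)
  acc1 <- acc2 <- numeric(B)
  acc_pop <- numeric(n_pop)
  batch <- 0L

  draws <- matrix(NA_real_, n_keep, P, dimnames = list(NULL,
                                                       bound$param_names))
  keep_row <- 0L
  tm <- plan$tau_members
  sm <- plan$sigma_members
  hp_mean <- bound$spec$hyperpriors$pop_mean

  mh_slot <- function(slot) {
    i_s <- if (slot == 1) blocks$i1 else blocks$i2
    pop_s <- if (slot == 1) blocks$pop1 else blocks$pop2
    coef_s <- if (slot == 1) blocks$coef1 else blocks$coef2
    tau_s <- if (slot == 1) blocks$tau1 else blocks$tau2
    step <- exp(if (slot == 1) ls1 else ls2)
    cur <- theta[i_s]
    prop <- cur + step * stats::rnorm(B)
    if (slot == 1) {
      ll_new <- cell_loglik(par_kind, prop[cells$block], theta[cells$i2],
                            cells$x, cells$y, cells$n, cells$lch)
    } else {
      ll_new <- cell_loglik(par_kind, theta[cells$i1], prop[cells$block],
                            cells$x, cells$y, cells$n, cells$lch)
    }
    d_ll <- as.vector(rowsum(cells$w * (ll_new - ll_cells), cells$block))
    sd_prior <- 1 / sqrt(theta[tau_s])
    mu_prior <- coef_s * theta[pop_s]
    d_prior <- stats::dnorm(prop, mu_prior, sd_prior, log = TRUE) -
      stats::dnorm(cur, mu_prior, sd_prior, log = TRUE)
    acc <- log(stats::runif(B)) < d_ll + d_prior
    theta[i_s[acc]] <<- prop[acc]
    sel <- acc[cells$block]
    ll_cells[sel] <<- ll_new[sel]
    acc
  }

  for (it in seq_len(n_total)) {
    a1 <- mh_slot(1)
    a2 <- mh_slot(2)

    # conjugate draws: population locations
    for (j in seq_along(plan$pop_children)) {
      ch <- plan$pop_children[[j]]
      prec0 <- theta[bound$pop$sigma_idx[j]]
      m0 <- if (is.na(bound$pop$parent_idx[j])) hp_mean else
        bound$pop$coef[j] * theta[bound$pop$parent_idx[j]]
      tau_ch <- theta[ch$tau]
      prec_like <- sum(tau_ch * ch$coef^2)
      num <- sum(tau_ch * ch$coef * theta[ch$idx])
      if (length(ch$pop_idx) > 0) {
        sg <- theta[ch$pop_sigma]
        prec_like <- prec_like + sum(sg * ch$pop_coef^2)
        num <- num + sum(sg * ch$pop_coef * theta[ch$pop_idx])
      }
      prec_post <- prec0 + prec_like
      theta[bound$pop$idx[j]] <- stats::rnorm(
        1, (prec0 * m0 + num) / prec_post, 1 / sqrt(prec_post))
    }

    # conjugate draws: first-stage precisions
    dev2 <- (theta[tm$idx] - tm$coef * theta[tm$pop])^2
    ssq <- as.vector(rowsum(dev2, tm$node))
    theta[bound$tau$idx] <- stats::rgamma(
      nrow(bound$tau), shape = bound$tau$shape + plan$tau_counts / 2,
      rate = bound$tau$rate + ssq / 2)

    # joint translation move per population location: shifts the location and
    # all its subject-level children together (deviations, and hence the
    # subject-level prior terms, are unchanged), decoupling the location's
    # mixing from the between-subject precision. Symmetric proposal, so the
    # ratio is likelihood change + the node's own prior change (+ the prior
    # change of dependent population children in joint models).
    for (j in seq_along(plan$pop_children)) {
      ch <- plan$pop_children[[j]]
      d_shift <- exp(ls_pop[j]) * stats::rnorm(1)
      v_old <- theta[bound$pop$idx[j]]
      v_new <- v_old + d_shift
      prop_vals <- theta[ch$idx] + ch$coef * d_shift
      theta_prop <- theta
      theta_prop[ch$idx] <- prop_vals
      cr <- ch$cells
      ll_new <- cell_loglik(par_kind, theta_prop[cells$i1[cr]],
                            theta_prop[cells$i2[cr]], cells$x[cr],
                            cells$y[cr], cells$n[cr], cells$lch[cr])
      d_ll <- sum(cells$w[cr] * (ll_new - ll_cells[cr]))
      m0 <- if (is.na(bound$pop$parent_idx[j])) hp_mean else
        bound$pop$coef[j] * theta[bound$pop$parent_idx[j]]
      sd0 <- 1 / sqrt(theta[bound$pop$sigma_idx[j]])
      log_r <- d_ll + stats::dnorm(v_new, m0, sd0, log = TRUE) -
        stats::dnorm(v_old, m0, sd0, log = TRUE)
      if (length(ch$pop_idx) > 0) {
        sdc <- 1 / sqrt(theta[ch$pop_sigma])
        log_r <- log_r +
          sum(stats::dnorm(theta[ch$pop_idx], ch$pop_coef * v_new, sdc,
                           log = TRUE)) -
          sum(stats::dnorm(theta[ch$pop_idx], ch$pop_coef * v_old, sdc,
                           log = TRUE))
      }
      acc_p <- log(stats::runif(1)) < log_r
      if (acc_p) {
        theta[ch$idx] <- prop_vals
        theta[bound$pop$idx[j]] <- v_new
        ll_cells[cr] <- ll_new
      }
      if (it <= config$n_warmup) acc_pop[j] <- acc_pop[j] + acc_p
    }

    # joint scale move per first-stage precision: rescales the subject
    # deviations and the precision together (tau' = tau / c^2, dev' = c dev),
    # which lets the sampler cross the hierarchical funnel that traps
    # componentwise updates when a precision drifts high while deviations
    # shrink. Metropolis ratio: likelihood ratio x Gamma prior ratio x
    # Jacobian; the normal kernel cancels exactly.
    for (k in seq_len(nrow(bound$tau))) {
      ts <- plan$tau_scale[[k]]
      eps <- stats::rnorm(1, 0, 0.4)
      cc <- exp(eps)
      tau_idx <- bound$tau$idx[k]
      tau_old <- theta[tau_idx]
      mu <- ts$coef * theta[ts$pop]
      prop_vals <- mu + cc * (theta[ts$idx] - mu)
      theta_prop <- theta
      theta_prop[ts$idx] <- prop_vals
      cr <- ts$cells
      ll_new <- cell_loglik(par_kind, theta_prop[cells$i1[cr]],
                            theta_prop[cells$i2[cr]], cells$x[cr],
                            cells$y[cr], cells$n[cr], cells$lch[cr])
      d_ll <- sum(cells$w[cr] * (ll_new - ll_cells[cr]))
      log_r <- d_ll - 2 * bound$tau$shape[k] * eps -
        bound$tau$rate[k] * tau_old * (cc^-2 - 1)
      if (log(stats::runif(1)) < log_r) {
        theta[ts$idx] <- prop_vals
        theta[tau_idx] <- tau_old / cc^2
        ll_cells[cr] <- ll_new
      }
    }

    # conjugate draws: population-location precisions
    pv <- rep(hp_mean, nrow(sm))
    pv[sm$has_parent] <- theta[sm$parent[sm$has_parent]]
    dev2s <- (theta[sm$idx] - sm$coef * pv)^2
    ssqs <- as.vector(rowsum(dev2s, sm$node))
    theta[bound$sigma$idx] <- stats::rgamma(
      nrow(bound$sigma), shape = bound$sigma$shape + plan$sigma_counts / 2,
      rate = bound$sigma$rate + ssqs / 2)

    # warmup adaptation of the random-walk steps (frozen afterwards)
    if (it <= config$n_warmup) {
      acc1 <- acc1 + a1
      acc2 <- acc2 + a2
      if (it %% 50 == 0) {
        batch <- batch + 1L
        delta <- max(0.05, min(0.7, 2 / sqrt(batch)))
        ls1 <- pmin(pmax(ls1 + delta * (acc1 / 50 - 0.44), -8), 4)
        ls2 <- pmin(pmax(ls2 + delta * (acc2 / 50 - 0.44), -8), 4)
        ls_pop <- pmin(pmax(ls_pop + delta * (acc_pop / 50 - 0.44), -8), 4)
        acc1[] <- 0
        acc2[] <- 0
        acc_pop[] <- 0
      }
    } else if ((it - config$n_warmup) %% config$thin == 0) {
      keep_row <- keep_row + 1L
      draws[keep_row, ] <- theta
    }
  }
  draws
}

#' Sample the posterior of a hierarchical psychometric model
#'
#' Runs an adaptive random-walk Metropolis-within-Gibbs sampler: subject-level
#' (location, slope) parameters are updated by vectorized random-walk
#' Metropolis steps (step sizes adapted during warmup, then frozen), while
#' population locations and all precision parameters have conjugate full
#' conditionals and are Gibbs-sampled exactly. With a [power_prior()], the
#' historical cells enter the Metropolis ratio with weight `a0`. Initial
#' states are drawn from the hyperpriors per chain unless `init` is given.
#' Identical (data, spec, config, power) inputs give bit-identical draws.
#'
#' @param data Current-study trial table.
#' @param spec A `psy_model` (bound internally) or a `psy_model_bound`.
#' @param config A [chain_config()].
#' @param power Optional [power_prior()].
#' @param historical Historical trial table (joint models only).
#' @param init Optional named numeric vector (or list of one per chain) of
#'   starting values.
#' @return An object of class `psy_fit` with elements `draws` (array
#'   iterations x chains x parameters), `spec` (the bound model), `data`,
#'   `config`, `power`, and `provenance`.
#' @export
run_chains <- function(data, spec, config = chain_config(), power = NULL,
                       historical = NULL, init = NULL) {
  bound <- if (inherits(spec, "psy_model_bound")) spec else
    bind_model(spec, data, power = power, historical = historical)
  stopifnot(inherits(config, "chain_config"))
  plan <- engine_plan(bound)
  P <- length(bound$param_names)
  draws <- array(NA_real_,
                 dim = c(config$n_iter, config$n_chains, P),
                 dimnames = list(NULL, NULL, bound$param_names))
  for (ch in seq_len(config$n_chains)) {
    chain_init <- if (is.list(init)) init[[ch]] else init
    draws[, ch, ] <- run_one_chain(bound, plan, config,
                                   chain_seed = config$seed + ch - 1L,
                                   init = chain_init)
  }
  structure(list(
    draws = draws, spec = bound, data = bound$data, config = config,
    power = power,
    provenance = list(
      sampler = "adaptive random-walk Metropolis-within-Gibbs",
      seed = config$seed,
      model_hash = rlang::hash(list(bound$param_names, bound$spec)),
      data_hash = rlang::hash(as.data.frame(bound$data)))
  ), class = "psy_fit")
}

#' @export
print.psy_fit <- function(x, ...) {
  d <- dim(x$draws)
  cat(sprintf("<psy_fit> %s model: %d parameters, %d chains x %d draws\n",
              x$spec$parameterization, d[3], d[2], d[1]))
  rh <- suppressWarnings(max(gelman_rubin(x), na.rm = TRUE))
  cat(sprintf("  max split R-hat: %.3f\n", rh))
  invisible(x)
}

# pooled draw matrix [S x P]
draw_matrix <- function(fit) {
  d <- fit$draws
  matrix(aperm(d, c(1, 2, 3)), nrow = dim(d)[1] * dim(d)[2],
         dimnames = list(NULL, dimnames(d)[[3]]))
}

#' Extract pooled posterior draws of one parameter
#'
#' @param fit A `psy_fit`.
#' @param parameter Canonical parameter name.
#' @return Numeric vector of pooled draws (all chains concatenated).
#' @export
draws_of <- function(fit, parameter) {
  nm <- dimnames(fit$draws)[[3]]
  if (!parameter %in% nm) {
    stop(sprintf("unknown parameter '%s'", parameter), call. = FALSE)
  }
  as.vector(fit$draws[, , parameter])
}

# ---- R-hat -----------------------------------------------------------------

rhat_classic <- function(mat) {
  n <- nrow(mat)
  W <- mean(apply(mat, 2, stats::var))
  Bv <- n * stats::var(colMeans(mat))
  if (!is.finite(W) || W == 0) return(1)
  sqrt(((n - 1) / n * W + Bv / n) / W)
}

rank_normalize <- function(mat) {
  S <- length(mat)
  z <- stats::qnorm((rank(mat, ties.method = "average") - 3 / 8) / (S + 1 / 4))
  matrix(z, nrow(mat), ncol(mat))
}

rhat_one <- function(mat) {
  if (stats::sd(as.vector(mat)) == 0) return(1)  # degenerate constant chains
  n2 <- floor(nrow(mat) / 2)
  split <- cbind(mat[seq_len(n2), , drop = FALSE],
                 mat[nrow(mat) - n2 + seq_len(n2), , drop = FALSE])
  bulk <- rhat_classic(rank_normalize(split))
  folded <- rhat_classic(rank_normalize(abs(split - stats::median(split))))
  max(bulk, folded)
}

#' Split rank-normalized Gelman-Rubin diagnostic
#'
#' Computes, per parameter, the split-chain rank-normalized R-hat (the
#' "recent version" of the Gelman-Rubin ratio of between- to within-chain
#' variance): chains are split in half, draws are rank-normalized, and the
#' classic ratio is computed on both the raw and the folded (median-absolute)
#' transformed draws; the larger of the two is reported. Values near 1
#' indicate convergence; a common threshold is 1.1. Chains that are constant
#' and identical return exactly 1 by convention.
#'
#' @param draws A `psy_fit`, or an array `[iterations, chains, parameters]`,
#'   or a matrix `[iterations, chains]` for a single parameter.
#' @return Named numeric vector of R-hat values (a single number for a
#'   matrix input).
#' @export
gelman_rubin <- function(draws) {
  if (inherits(draws, "psy_fit")) draws <- draws$draws
  if (is.matrix(draws)) {
    if (ncol(draws) < 2) {
      stop("R-hat requires n_chains >= 2", call. = FALSE)
    }
    if (nrow(draws) < 4) stop("R-hat requires >= 4 iterations", call. = FALSE)
    return(rhat_one(draws))
  }
  stopifnot(length(dim(draws)) == 3)
  if (dim(draws)[2] < 2) stop("R-hat requires n_chains >= 2", call. = FALSE)
  if (dim(draws)[1] < 4) stop("R-hat requires >= 4 iterations", call. = FALSE)
  out <- vapply(seq_len(dim(draws)[3]),
                function(p) rhat_one(draws[, , p, drop = TRUE]), numeric(1))
  stats::setNames(out, dimnames(draws)[[3]])
}

# ---- posterior summaries ---------------------------------------------------

# Augment a draw array with derived PSE parameters for intercept/slope models.
augment_derived <- function(fit) {
  d <- fit$draws
  if (fit$spec$parameterization != "intercept_slope") return(d)
  nm <- dimnames(d)[[3]]
  blocks <- fit$spec$blocks
  extra <- list()
  for (r in seq_len(nrow(blocks))) {
    new <- sub("^alpha", "pse", blocks$p1_name[r])
    extra[[new]] <- -d[, , blocks$p1_name[r]] / d[, , blocks$p2_name[r]]
  }
  pop <- fit$spec$pop
  loc1 <- grepl("^a0?\\[", pop$name)
  for (r in which(loc1)) {
    slope_name <- sub("^a", "b", pop$name[r])
    if (slope_name %in% pop$name) {
      new <- sub("^a", "PSE", pop$name[r])
      extra[[new]] <- -d[, , pop$name[r]] / d[, , slope_name]
    }
  }
  if (length(extra) == 0) return(d)
  out <- array(NA_real_, dim = dim(d) + c(0, 0, length(extra)),
               dimnames = list(NULL, NULL, c(nm, names(extra))))
  out[, , nm] <- d
  for (nm2 in names(extra)) out[, , nm2] <- extra[[nm2]]
  out
}

#' Summarize posterior draws
#'
#' Pools draws across chains and reports, per parameter: posterior mean, sd,
#' 2.5/50/97.5 percentiles, the central credible interval at `level`
#' (empirical percentiles with linear interpolation), its width, and split
#' rank-normalized R-hat. For intercept/slope models the per-subject and
#' population PSE (`-alpha/beta`, computed draw by draw, never from
#' parameter means) are appended as derived rows.
#'
#' @param fit A `psy_fit`.
#' @param level Credible-interval level in (0, 1), default 0.95.
#' @return A tibble with one row per parameter.
#' @export
summarize_posterior <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "psy_fit"))
  if (!is.numeric(level) || length(level) != 1 || level <= 0 || level >= 1) {
    stop("level must be in (0, 1)", call. = FALSE)
  }
  d <- augment_derived(fit)
  nm <- dimnames(d)[[3]]
  a <- (1 - level) / 2
  rows <- purrr::map(seq_along(nm), function(p) {
    x <- as.vector(d[, , p])
    q <- stats::quantile(x, c(0.025, 0.5, 0.975, a, 1 - a), names = FALSE)
    tibble::tibble(
      parameter = nm[p], mean = mean(x), sd = stats::sd(x),
      q2.5 = q[1], median = q[2], q97.5 = q[3],
      ci_low = q[4], ci_high = q[5], ci_width = q[5] - q[4],
      rhat = rhat_one(d[, , p, drop = TRUE]))
  })
  dplyr::bind_rows(rows)
}

# ---- generic adaptive random-walk sampler (used for validation targets) ----

#' Adaptive random-walk Metropolis sampler for an arbitrary log-density
#'
#' A small general-purpose sampler sharing the adaptive random-walk kernel of
#' [run_chains()]: componentwise Gaussian proposals whose log step sizes adapt
#' toward a 44% acceptance rate during warmup. Intended for low-dimensional
#' targets (e.g. validating the kernel on conjugate problems with known
#' posteriors).
#'
#' @param log_density Function taking a numeric vector, returning the target
#'   log-density (may be `-Inf` outside the support).
#' @param init Numeric vector: initial state (recycled to all chains), or a
#'   list of one initial state per chain.
#' @param n_iter Kept iterations per chain.
#' @param n_warmup Warmup iterations.
#' @param n_chains Number of chains.
#' @param seed Master seed.
#' @param step0 Initial step size.
#' @return Array `[n_iter, n_chains, d]`.
#' @export
mcmc_rw <- function(log_density, init, n_iter = 2000, n_warmup = 1000,
                    n_chains = 4, seed = 1, step0 = 0.5) {
  inits <- if (is.list(init)) init else rep(list(init), n_chains)
  stopifnot(length(inits) == n_chains)
  d <- length(inits[[1]])
  out <- array(NA_real_, dim = c(n_iter, n_chains, d))
  for (ch in seq_len(n_chains)) {
    set.seed(seed + ch - 1L)
    x <- as.numeric(inits[[ch]])
    lp <- log_density(x)
    ls <- rep(log(step0), d)
    acc <- numeric(d)
    batch <- 0L
    for (it in seq_len(n_warmup + n_iter)) {
      for (k in seq_len(d)) {
        prop <- x
        prop[k] <- x[k] + exp(ls[k]) * stats::rnorm(1)
        lp_new <- log_density(prop)
        if (log(stats::runif(1)) < lp_new - lp) {
          x <- prop
          lp <- lp_new
          acc[k] <- acc[k] + 1
        }
      }
      if (it <= n_warmup && it %% 50 == 0) {
        batch <- batch + 1L
        delta <- max(0.05, min(0.7, 2 / sqrt(batch)))
        ls <- pmin(pmax(ls + delta * (acc / 50 - 0.44), -8), 4)
        acc[] <- 0
      }
      if (it > n_warmup) out[it - n_warmup, ch, ] <- x
    }
  }
  out
}
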