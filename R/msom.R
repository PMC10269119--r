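#' Enumerate latent presence states
#'
#' All 2^S presence/absence vectors over S guilds, in canonical binary-
#' counting order with guild 1 as the least significant bit, e.g. for S = 2:
#' (0,0), (1,0), (0,1), (1,1). The order is stable across calls and is the
#' order used by [state_probabilities()].
#'
#' @param S Number of guilds (1 to 4).
#' @return A 2^S x S integer matrix of 0/1 entries.
#' @export
enumerate_states <- function(S) {
  if (!is.numeric(S) || length(S) != 1 || S < 1 || S > 4 || S != round(S)) {
    stop("S must be an integer between 1 and 4")
  }
  S <- as.integer(S)
  idx <- 0:(2^S - 1)
  m <- vapply(seq_len(S), function(s) as.integer((idx %/% 2^(s - 1)) %% 2), integer(2^S))
  m <- matrix(m, nrow = 2^S, ncol = S)
  colnames(m) <- paste0("z", seq_len(S))
  m
}

#' Construct natural parameters
#'
#' The multinomial-logit distribution over the 2^S latent presence states is
#' parameterised by first-order natural parameters f_s (one per guild; the
#' log-odds of guild s occurring alone, relative to the empty state) and
#' optional second-order parameters f_jk for each unordered guild pair
#' (log-linear co-occurrence terms; f_jk > 0 means the pair co-occurs more
#' than independence predicts).
#'
#' @param first_order Named numeric vector, one entry per guild.
#' @param second_order Optional named numeric vector of pairwise terms; names
#'   must be `"a:b"` with `a`, `b` guild names in first-order order. Missing
#'   pairs default to 0 when any are supplied; `NULL` means a first-order
#'   (no-interaction) model.
#' @return A `natural_params` object.
#' @export
natural_params <- function(first_order, second_order = NULL) {
  if (is.null(names(first_order)) || any(!nzchar(names(first_order)))) {
    stop("first_order must be a named vector of guild effects")
  }
  if (any(!is.finite(first_order))) stop("natural parameters must be finite")
  guilds <- names(first_order)
  S <- length(guilds)
  if (S < 1 || S > 4) stop("between 1 and 4 guilds supported")
  pairs <- pair_names(guilds)
  if (!is.null(second_order)) {
    if (any(!is.finite(second_order))) stop("natural parameters must be finite")
    extra <- setdiff(names(second_order), pairs)
    if (length(extra) > 0) stop("unknown pair name(s): ", paste(extra, collapse = ", "))
    full <- stats::setNames(rep(0, length(pairs)), pairs)
    full[names(second_order)] <- second_order
    second_order <- full
  }
  structure(list(first_order = first_order, second_order = second_order,
                 guilds = guilds),
            class = "natural_params")
}

pair_names <- function(guilds) {
  S <- length(guilds)
  if (S < 2) return(character(0))
  idx <- utils::combn(S, 2)
  paste(guilds[idx[1, ]], guilds[idx[2, ]], sep = ":")
}

#' @export
print.natural_params <- function(x, ...) {
  cat("<natural_params>", length(x$guilds), "guilds:",
      paste(x$guilds, collapse = ", "), "\n")
  cat("first order: ", paste(sprintf("%s=%.3f", x$guilds, x$first_order), collapse = "  "), "\n")
  if (!is.null(x$second_order)) {
    cat("second order:", paste(sprintf("%s=%.3f", names(x$second_order), x$second_order),
                               collapse = "  "), "\n")
  }
  invisible(x)
}

# log-weights over states for given f, states from enumerate_states()
state_log_weights <- function(f, states = NULL) {
  S <- length(f$guilds)
  if (is.null(states)) states <- enumerate_states(S)
  lw <- drop(states %*% f$first_order)
  if (!is.null(f$second_order) && S >= 2) {
    idx <- utils::combn(S, 2)
    for (j in seq_len(ncol(idx))) {
      lw <- lw + f$second_order[j] * states[, idx[1, j]] * states[, idx[2, j]]
    }
  }
  unname(lw)
}

#' Multinomial-logit state distribution
#'
#' Maps natural parameters to the probability of each latent presence state:
#' P(z) proportional to exp(sum_s f_s z_s + sum_(j<k) f_jk z_j z_k), with the
#' all-absent state carrying weight exp(0) = 1.
#'
#' @param f A [natural_params()] object.
#' @return A tibble with one 0/1 column per guild and a `probability` column,
#'   rows in [enumerate_states()] order, probabilities summing to 1.
#' @examples
#' f <- natural_params(c(prey = 0.5, human = -0.3), c("prey:human" = 1.0))
#' state_probabilities(f)
#' @export
state_probabilities <- function(f) {
  stopifnot(inherits(f, "natural_params"))
  states <- enumerate_states(length(f$guilds))
  p <- state_prob_vector(f, states)
  out <- tibble::as_tibble(states)
  names(out) <- f$guilds
  out$probability <- p
  out
}

state_prob_vector <- function(f, states = NULL) {
  lw <- state_log_weights(f, states)
  w <- exp(lw - max(lw))
  w / sum(w)
}

#' Marginal likelihood of one site's detection data
#'
#' The occupancy mixture likelihood for a single site: a sum over the 2^S
#' latent presence states of the state probability times, per guild, the
#' occasion-wise Bernoulli detection probability (p_s^y (1-p_s)^(K_s - y)
#' when the guild is present; the indicator of zero detections when absent).
#' No binomial coefficient appears: the likelihood is exact for the ordered
#' detection history, and with constant per-occasion p it depends on the
#' history only through the detection count.
#'
#' @param y Integer vector of detection counts, one per guild.
#' @param k Integer vector of non-missing occasion counts per guild (recycled
#'   if length 1).
#' @param p Numeric vector of per-occasion detection probabilities in (0,1).
#' @param dist State distribution: a [state_probabilities()] tibble or a
#'   plain probability vector in canonical state order.
#' @return The site likelihood, a probability.
#' @export
site_likelihood <- function(y, k, p, dist) {
  if (is.data.frame(dist)) dist <- dist$probability
  S <- as.integer(log2(length(dist)))
  if (length(k) == 1) k <- rep(k, S)
  stopifnot(length(y) == S, length(k) == S, length(p) == S)
  if (any(y < 0) || any(y > k)) stop("detection counts must lie in 0..K_s")
  if (any(k == 0 & y > 0)) stop("detection recorded for a guild with no active occasions")
  states <- enumerate_states(S)
  g1 <- p^y * (1 - p)^(k - y)       # per-guild likelihood given presence
  g0 <- as.numeric(y == 0)          # given absence: only all-zero history possible
  per_state <- apply(states, 1, function(z) prod(ifelse(z == 1, g1, g0)))
  sum(dist * per_state)
}

# ---- internal likelihood machinery ------------------------------------------

# theta packing: (f_1..f_S, [f_jk j<k], qlogis(p_1..p_S))
theta_names <- function(guilds, interaction_order) {
  c(paste0("f[", guilds, "]"),
    if (interaction_order == 2) paste0("f[", pair_names(guilds), "]"),
    paste0("logit_p[", guilds, "]"))
}

unpack_theta <- function(theta, guilds, interaction_order) {
  S <- length(guilds)
  f1 <- stats::setNames(theta[seq_len(S)], guilds)
  off <- S
  f2 <- NULL
  if (interaction_order == 2) {
    npair <- S * (S - 1) / 2
    f2 <- stats::setNames(theta[off + seq_len(npair)], pair_names(guilds))
    off <- off + npair
  }
  p <- stats::plogis(theta[off + seq_len(S)])
  list(f = natural_params(f1, f2), p = stats::setNames(p, guilds))
}

# Sufficient statistics: per-site detection count and active-occasion count
# per guild (constant p makes the occasion-wise Bernoulli product depend on
# the history only through these).
history_stats <- function(histories) {
  n <- nrow(histories[[1]])
  y <- matrix(unlist(lapply(histories, function(h) rowSums(h == 1L, na.rm = TRUE))), nrow = n)
  k <- matrix(unlist(lapply(histories, function(h) rowSums(!is.na(h)))), nrow = n)
  list(y = y, k = k)  # each n_sites x S
}

# Vectorised negative log-likelihood over sites.
msom_negloglik <- function(theta, stats, guilds, interaction_order, states) {
  pars <- unpack_theta(theta, guilds, interaction_order)
  pz <- state_prob_vector(pars$f, states)
  S <- length(guilds)
  n <- nrow(stats$y)
  # per-guild site likelihood given presence / absence
  lg1 <- matrix(0, n, S)
  g0 <- matrix(0, n, S)
  for (s in seq_len(S)) {
    p <- pars$p[s]
    lg1[, s] <- stats$y[, s] * log(p) + (stats$k[, s] - stats$y[, s]) * log1p(-p)
    g0[, s] <- as.numeric(stats$y[, s] == 0)
  }
  g1 <- exp(lg1)
  lik <- numeric(n)
  for (r in seq_len(nrow(states))) {
    contrib <- rep(pz[r], n)
    for (s in seq_len(S)) {
      contrib <- contrib * (if (states[r, s] == 1L) g1[, s] else g0[, s])
    }
    lik <- lik + contrib
  }
  if (any(lik <= 0) || any(!is.finite(lik))) return(1e10)
  -sum(log(lik))
}

#' Fit the multispecies occupancy model
#'
#' Maximum-likelihood fit of the multinomial-logit co-occurrence occupancy
#' model with imperfect detection: latent guild presence at each site follows
#' [state_probabilities()] under the natural parameters, and detection is
#' occasion-wise Bernoulli with a constant per-guild probability p_s. The
#' likelihood is maximised by BFGS from several jittered starts (seeded); the
#' covariance matrix is the inverse observed information at the optimum.
#'
#' @param histories Named list of detection histories (matrices or
#'   [build_detection_history()] objects), one per guild, sharing the site
#'   dimension; names are the guild names, in model order.
#' @param interaction_order 1 (independent guilds) or 2 (all pairwise
#'   co-occurrence terms).
#' @param n_starts Number of optimiser starts (>= 1; first start is
#'   deterministic, later ones jittered).
#' @param seed Integer seed for the start jitter.
#' @param control Passed to [stats::optim()] (maxit defaults to 500).
#' @return An `msom_fit` with elements `estimates` (named vector on the
#'   estimation scale), `params` (a [natural_params()]), `detection`
#'   (per-guild p), `vcov`, `loglik`, `aic`, `n_params`, `convergence`
#'   (code, gradient norm), and the model `spec`.
#' @export
fit_msom <- function(histories, interaction_order = 2, n_starts = 3, seed = 1,
                     control = list()) {
  if (is.null(names(histories)) || any(!nzchar(names(histories)))) {
    stop("histories must be a named list (names = guild names)")
  }
  if (!interaction_order %in% c(1, 2)) stop("interaction_order must be 1 or 2")
  histories <- lapply(histories, function(h) {
    m <- unclass(h)
    storage.mode(m) <- "integer"
    m
  })
  dims <- vapply(histories, nrow, integer(1))
  if (length(unique(dims)) != 1) stop("all histories must share the site dimension")
  guilds <- names(histories)
  S <- length(guilds)
  if (S < 2) stop("at least two guilds required")
  st <- history_stats(histories)
  zero_det <- colSums(st$y) == 0
  if (any(zero_det)) {
    warning("guild(s) with zero detections: ", paste(guilds[zero_det], collapse = ", "))
  }
  states <- enumerate_states(S)
  npar <- S + (if (interaction_order == 2) S * (S - 1) / 2 else 0) + S
  # deterministic start: f = 0, p = overall naive per-occasion detection rate
  p0 <- pmin(pmax(colSums(st$y) / pmax(colSums(st$k), 1), 0.05), 0.95)
  start0 <- c(rep(0, npar - S), stats::qlogis(p0))
  control <- utils::modifyList(list(maxit = 1000, reltol = 1e-12), control)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  starts <- list(start0)
  if (n_starts > 1) {
    for (j in seq_len(n_starts - 1)) {
      starts[[j + 1]] <- start0 + stats::rnorm(npar, 0, 0.5)
    }
  }
  fits <- lapply(starts, function(s0) {
    tryCatch(
      stats::optim(s0, msom_negloglik, stats = st, guilds = guilds,
                   interaction_order = interaction_order, states = states,
                   method = "BFGS", control = control, hessian = FALSE),
      error = function(e) NULL
    )
  })
  fits <- Filter(function(f) !is.null(f) && is.finite(f$value) && f$value < 1e9, fits)
  if (length(fits) == 0) stop("MSOM fit failed: no optimiser start converged")
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  theta <- best$par
  names(theta) <- theta_names(guilds, interaction_order)
  nll <- function(x) msom_negloglik(x, st, guilds, interaction_order, states)
  grad <- numeric_gradient(nll, theta)
  hess <- tryCatch(stats::optimHess(theta, nll), error = function(e) NULL)
  vcov <- NULL
  singular <- FALSE
  if (!is.null(hess)) {
    vcov <- tryCatch(solve(hess), error = function(e) NULL)
  }
  if (is.null(vcov) || any(!is.finite(vcov)) || any(diag(vcov) < 0)) {
    warning("observed information is singular; interval methods disabled")
    singular <- TRUE
    vcov <- matrix(NA_real_, length(theta), length(theta))
  } else {
    vcov <- (vcov + t(vcov)) / 2
  }
  dimnames(vcov) <- list(names(theta), names(theta))
  pars <- unpack_theta(theta, guilds, interaction_order)
  loglik <- -best$value
  structure(list(
    spec = list(guild_names = guilds, interaction_order = interaction_order,
                n_occasions = ncol(histories[[1]]), n_sites = dims[[1]]),
    estimates = theta,
    params = pars$f,
    detection = pars$p,
    vcov = vcov,
    loglik = loglik,
    aic = 2 * length(theta) - 2 * loglik,
    n_params = length(theta),
    convergence = list(code = best$convergence,
                       gradient_norm = sqrt(sum(grad^2)),
                       n_starts_ok = length(fits),
                       singular_information = singular)
  ), class = "msom_fit")
}

numeric_gradient <- function(fn, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    e <- numeric(length(x)); e[i] <- h
    (fn(x + e) - fn(x - e)) / (2 * h)
  }, numeric(1))
}

#' @export
print.msom_fit <- function(x, ...) {
  cat("<msom_fit>", length(x$spec$guild_names), "guilds,",
      if (x$spec$interaction_order == 2) "pairwise interactions," else "no interactions,",
      x$spec$n_sites, "sites x", x$spec$n_occasions, "occasions\n")
  cat(sprintf("logLik %.3f | AIC %.3f | k = %d | grad norm %.2e\n",
              x$loglik, x$aic, x$n_params, x$convergence$gradient_norm))
  print(x$params)
  cat("detection p: ", paste(sprintf("%s=%.3f", names(x$detection), x$detection),
                             collapse = "  "), "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.msom_fit <- function(x, ...) {
  se <- sqrt(diag(x$vcov))
  tibble::tibble(term = names(x$estimates), estimate = unname(x$estimates),
                 std.error = unname(se),
                 statistic = unname(x$estimates / se),
                 p.value = 2 * stats::pnorm(-abs(unname(x$estimates / se))))
}

#' @export
glance.msom_fit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, AIC = x$aic, df = x$n_params,
                 n_sites = x$spec$n_sites, n_occasions = x$spec$n_occasions,
                 converged = x$convergence$code == 0)
}

#' Rank occupancy models by AIC
#'
#' @param ... `msom_fit` objects (optionally named), or a single list of them.
#' @return A tibble sorted by AIC (ties broken by fewer parameters) with
#'   `delta_aic` relative to the best model and a `best` flag.
#' @export
compare_models <- function(...) {
  fits <- list(...)
  if (length(fits) == 1 && is.list(fits[[1]]) && !inherits(fits[[1]], "msom_fit")) {
    fits <- fits[[1]]
  }
  stopifnot(length(fits) >= 1, all(vapply(fits, inherits, logical(1), "msom_fit")))
  dims <- vapply(fits, function(f) paste(f$spec$n_sites, f$spec$n_occasions), character(1))
  if (length(unique(dims)) != 1) stop("models were fitted to data of different dimensions")
  nm <- names(fits)
  if (is.null(nm) || any(!nzchar(nm))) {
    nm <- vapply(fits, function(f) {
      if (f$spec$interaction_order == 2) "pairwise_interaction" else "no_interaction"
    }, character(1))
    nm <- make.unique(nm)
  }
  out <- tibble::tibble(
    model = unname(nm),
    k = unname(vapply(fits, `[[`, numeric(1), "n_params")),
    logLik = unname(vapply(fits, `[[`, numeric(1), "loglik")),
    AIC = unname(vapply(fits, `[[`, numeric(1), "aic"))
  ) |>
    dplyr::arrange(.data$AIC, .data$k) |>
    dplyr::mutate(delta_aic = .data$AIC - .data$AIC[1],
                  best = dplyr::row_number() == 1)
  out
}

# ---- derived occupancy quantities -------------------------------------------

# q: function(theta) -> probability; delta-method or normal-resampling CI.
derived_quantity <- function(fit, q, label, guilds_involved,
                             conf_level = 0.95, method = c("delta", "boot"),
                             B = 1000, seed = 1) {
  method <- match.arg(method)
  est <- q(fit$estimates)
  alpha <- 1 - conf_level
  if (fit$convergence$singular_information) {
    return(tibble::tibble(quantity = label, guilds = guilds_involved,
                          estimate = est, se = NA_real_,
                          ci_low = NA_real_, ci_high = NA_real_,
                          conf_level = conf_level, method = method))
  }
  if (method == "delta") {
    g <- numeric_gradient(q, fit$estimates, h = 1e-5)
    v <- drop(t(g) %*% fit$vcov %*% g)
    se <- sqrt(max(v, 0))
    lo <- max(0, est + stats::qnorm(alpha / 2) * se)
    hi <- min(1, est + stats::qnorm(1 - alpha / 2) * se)
  } else {
    set.seed(as.integer(seed) %% .Machine$integer.max)
    L <- chol(fit$vcov)
    draws <- matrix(stats::rnorm(B * length(fit$estimates)), B) %*% L
    qs <- apply(draws, 1, function(d) q(fit$estimates + d))
    se <- stats::sd(qs)
    ci <- stats::quantile(qs, c(alpha / 2, 1 - alpha / 2), names = FALSE)
    lo <- max(0, ci[1]); hi <- min(1, ci[2])
  }
  tibble::tibble(quantity = label, guilds = guilds_involved, estimate = est,
                 se = se, ci_low = lo, ci_high = hi,
                 conf_level = conf_level, method = method)
}

fit_state_probs <- function(fit, theta = fit$estimates) {
  pars <- unpack_theta(theta, fit$spec$guild_names, fit$spec$interaction_order)
  state_prob_vector(pars$f)
}

guild_index <- function(fit, guild) {
  i <- match(guild, fit$spec$guild_names)
  if (is.na(i)) stop("unknown guild: ", guild)
  i
}

#' Marginal occupancy of one guild
#'
#' psi_s = sum of state probabilities over states with guild s present,
#' evaluated at the MLE, with a delta-method (default) or normal-resampling
#' interval truncated to \[0, 1\].
#'
#' @param fit An `msom_fit`.
#' @param guild Guild name.
#' @param conf_level Interval coverage (default 0.95).
#' @param method `"delta"` or `"boot"` (resample estimates from the
#'   asymptotic normal, percentile interval).
#' @param B,seed Resampling controls for `method = "boot"`.
#' @return A one-row tibble: quantity, guilds, estimate, se, ci_low, ci_high.
#' @export
marginal_occupancy <- function(fit, guild, conf_level = 0.95,
                               method = c("delta", "boot"), B = 1000, seed = 1) {
  s <- guild_index(fit, guild)
  states <- enumerate_states(length(fit$spec$guild_names))
  q <- function(theta) sum(fit_state_probs(fit, theta)[states[, s] == 1])
  derived_quantity(fit, q, "marginal", guild, conf_level, method, B, seed)
}

#' Co-occurrence probability of two guilds
#'
#' P(z_s = 1, z_t = 1): the probability both guilds occupy a site.
#'
#' @inheritParams marginal_occupancy
#' @param guild,with Two distinct guild names.
#' @return A one-row tibble as in [marginal_occupancy()].
#' @export
cooccurrence_probability <- function(fit, guild, with, conf_level = 0.95,
                                     method = c("delta", "boot"), B = 1000, seed = 1) {
  s <- guild_index(fit, guild); t <- guild_index(fit, with)
  if (s == t) stop("guilds must differ")
  states <- enumerate_states(length(fit$spec$guild_names))
  sel <- states[, s] == 1 & states[, t] == 1
  q <- function(theta) sum(fit_state_probs(fit, theta)[sel])
  derived_quantity(fit, q, "cooccurrence", paste(guild, with, sep = ":"),
                   conf_level, method, B, seed)
}

#' Conditional occupancy of one guild given another
#'
#' P(z_s = 1 | z_t = present), the occupancy of guild s at sites where guild
#' t is present (or absent). This is the quantity behind "occupancy of prey
#' conditional on the presence of humans".
#'
#' @inheritParams marginal_occupancy
#' @param guild Focal guild s.
#' @param given Conditioning guild t.
#' @param present Condition on presence (`TRUE`, default) or absence.
#' @return A one-row tibble as in [marginal_occupancy()].
#' @export
conditional_occupancy <- function(fit, guild, given, present = TRUE,
                                  conf_level = 0.95, method = c("delta", "boot"),
                                  B = 1000, seed = 1) {
  s <- guild_index(fit, guild); t <- guild_index(fit, given)
  if (s == t) stop("guilds must differ")
  states <- enumerate_states(length(fit$spec$guild_names))
  cond <- if (present) states[, t] == 1 else states[, t] == 0
  joint <- cond & states[, s] == 1
  q <- function(theta) {
    pz <- fit_state_probs(fit, theta)
    denom <- sum(pz[cond])
    if (denom < 1e-12) stop("conditioning event has vanishing probability")
    sum(pz[joint]) / denom
  }
  lbl <- paste0(guild, "|", given, "=", if (present) "present" else "absent")
  derived_quantity(fit, q, "conditional", lbl, conf_level, method, B, seed)
}

#' All derived occupancy quantities of a fit
#'
#' Stacks marginal occupancy per guild, pairwise co-occurrence with each
#' other guild, and conditional occupancy given each other guild's presence
#' and absence, in one tidy table.
#'
#' @inheritParams marginal_occupancy
#' @return A tibble, one row per quantity.
#' @export
occupancy_estimates <- function(fit, conf_level = 0.95,
                                method = c("delta", "boot"), B = 1000, seed = 1) {
  g <- fit$spec$guild_names
  rows <- list()
  for (s in g) rows[[length(rows) + 1]] <- marginal_occupancy(fit, s, conf_level, method, B, seed)
  if (length(g) >= 2) {
    prs <- utils::combn(g, 2)
    for (j in seq_len(ncol(prs))) {
      rows[[length(rows) + 1]] <- cooccurrence_probability(fit, prs[1, j], prs[2, j],
                                                           conf_level, method, B, seed)
    }
    for (s in g) for (t in setdiff(g, s)) {
      rows[[length(rows) + 1]] <- conditional_occupancy(fit, s, t, TRUE, conf_level, method, B, seed)
      rows[[length(rows) + 1]] <- conditional_occupancy(fit, s, t, FALSE, conf_level, method, B, seed)
    }
  }
  dplyr::bind_rows(rows)
}
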