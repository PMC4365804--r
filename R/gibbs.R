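## Truncated blocked Gibbs sampler for the hierarchical Dirichlet process
## mixture of negative binomials.
##
## Finite two-layer stick-breaking representation.  A shared dictionary of
## K global atoms carries the fold-change values; the global measure G0 is
## approximated by w ~ Dirichlet(delta/K, ..., delta/K) over the
## dictionary.  Each group l has its own T group-level clusters
## ("tables"): table weights tw_l ~ Dirichlet(gamma_l/T, ..., gamma_l/T),
## and every table maps to a global atom through c[l, t] ~ Categorical(w).
## A gene's indicator in group l is z[i, l] = c[l, t[i, l]] where
## t[i, l] ~ Categorical(tw_l).  Updating c moves a whole group cluster to
## another global atom in one blocked draw, which is what lets duplicate
## atoms merge (a one-layer collapsed scheme gets stuck in configurations
## where two groups use different but numerically equal atoms, turning
## every gene into a false discovery).
##
## One sweep updates, in order: table indicators t (blocked, all (i, l)
## from the same pre-update weights/maps/atoms) -> weights and maps
## (c given w, table weights, global weights) -> atoms (random-walk MH;
## unoccupied atoms redrawn from H) -> gene parameters (log phi by
## random-walk MH, p by an independence MH whose proposal is the
## exposure-1 conjugate Beta, exact when all effective exposures
## c_j * exp(beta) equal 1) -> hyperparameters (Normal-Inverse-Gamma
## conditionals, Escobar-West concentration draws; unoccupied atoms are
## refreshed from the new base measure immediately afterwards, keeping the
## occupied-atoms-only conditional exact).

#' Sampler configuration
#'
#' @param trunc truncation level K of the shared atom dictionary, also
#'   used as the per-group table truncation (>= 2).
#' @param n_iter total number of Gibbs sweeps.
#' @param burn_in sweeps discarded before samples are stored
#'   (`0 <= burn_in < n_iter`).  Proposal scales adapt only during burn-in.
#' @param thin keep every `thin`-th post-burn-in sweep.
#' @param atom_scale,phi_scale initial random-walk standard deviations for
#'   the atom and log-dispersion Metropolis steps; adapted toward ~30%
#'   acceptance during burn-in, frozen afterwards.
#' @param conc_shape,conc_rate Gamma hyperprior on each DP concentration
#'   (group-level gamma_l and global delta); default Gamma(1, 1).
#' @param nig Normal-Inverse-Gamma hyperprior `c(m0, k0, a0, b0)` shared by
#'   the base-measure parameters (mu_beta, sigma2_beta) and the dispersion
#'   prior parameters (mu_phi, sigma2_phi).
#' @param seed integer root seed; every random draw in the chain derives
#'   from it.
#' @param checkpoint_every write a resumable checkpoint every this many
#'   sweeps when the chain is run with a `store` directory.
#' @param store_phi also record thinned dispersion samples.
#' @return a list of class `sampler_config`.
#' @export
sampler_config <- function(trunc = 100L, n_iter = 10000L, burn_in = 5000L,
                           thin = 1L, atom_scale = 0.5, phi_scale = 0.5,
                           conc_shape = 1, conc_rate = 1,
                           nig = c(m0 = 0, k0 = 0.01, a0 = 2, b0 = 2),
                           seed = 1L, checkpoint_every = 1000L,
                           store_phi = TRUE) {
  trunc <- as.integer(trunc); n_iter <- as.integer(n_iter)
  burn_in <- as.integer(burn_in); thin <- as.integer(thin)
  if (trunc < 2L) stop("truncation level must be >= 2")
  if (n_iter < 1L) stop("n_iter must be >= 1")
  if (burn_in < 0L || burn_in >= n_iter)
    stop("burn_in must satisfy 0 <= burn_in < n_iter")
  if (thin < 1L) stop("thin must be >= 1")
  if (atom_scale < 0 || phi_scale < 0) stop("proposal scales must be >= 0")
  structure(list(trunc = trunc, n_iter = n_iter, burn_in = burn_in,
                 thin = thin, atom_scale = atom_scale, phi_scale = phi_scale,
                 conc_shape = conc_shape, conc_rate = conc_rate,
                 nig = nig, seed = as.integer(seed),
                 checkpoint_every = as.integer(checkpoint_every),
                 store_phi = isTRUE(store_phi)),
            class = "sampler_config")
}

## Internal bundle of data-side quantities consumed by the updates.
build_model <- function(counts, groups, norm) {
  stopifnot(inherits(counts, "count_matrix"), inherits(groups, "group_map"))
  y <- counts$counts
  if (length(groups$group) != ncol(y))
    stop("group map length does not match the number of libraries")
  if (is.null(norm)) norm <- size_factors(counts)
  if (length(norm) != ncol(y))
    stop("normalisation factor length does not match libraries")
  zero <- rowSums(y) == 0
  if (any(zero))
    stop(sprintf(paste0("%d gene(s) have zero total count (e.g. '%s'); ",
                        "filter zero-sum rows before running the sampler ",
                        "(see read_counts(filter_zero_rows = TRUE))"),
                 sum(zero), counts$gene_ids[which(zero)[1]]))
  list(y = y, N = nrow(y), M = ncol(y), L = groups$n_groups,
       lambda = groups$group, cf = as.numeric(norm),
       group_names = groups$group_names, gene_ids = counts$gene_ids)
}

## Per-group N x K atom log-likelihood, cached across the updates of one
## sweep (the cache is dropped whenever atoms or gene parameters move).
atom_loglik <- function(state, model) {
  ll <- state$cache_ll
  if (is.null(ll)) {
    ll <- cpp_atom_loglik(model$y, exp(state$log_phi), state$mu, model$cf,
                          model$lambda, model$L, state$atoms)
  }
  ll
}

#' Initialise the sampler state
#'
#' Method-of-moments start: per-gene dispersions from the mean/variance of
#' normalised counts (floored at 1e-3), `p_i` by inverting the mean
#' reparameterisation at the normalised gene mean, all indicators in table
#' 1 of their group with every table initially mapped to atom 1, atoms
#' drawn from the base measure, uniform weights.  Sets the RNG from
#' `config$seed`, so the state is reproducible.
#'
#' @param counts a [count_matrix()]; rows with zero total count are an
#'   error.
#' @param groups a [group_map()].
#' @param norm [norm_factors()] or `NULL` for [size_factors()].
#' @param config a [sampler_config()].
#' @return a list of class `chain_state` with, among others, the table
#'   indicators `t` (N x L), table-to-atom maps `c` (L x T), table weights
#'   `tw` (L x T), global weights `w` (K), atoms (K) and the derived
#'   indicator matrix `z = c[l, t[i, l]]`.
#' @export
init_state <- function(counts, groups, norm = NULL, config = sampler_config()) {
  model <- build_model(counts, groups, norm)
  set.seed(config$seed)
  K <- config$trunc
  xn <- sweep(model$y, 2, model$cf, "/")
  gm <- rowMeans(xn)
  v <- apply(xn, 1, var)
  phi <- pmin(pmax((v - gm) / gm^2, 1e-3), 1e3)
  phi[!is.finite(phi)] <- 1e-3
  log_phi <- log(phi)
  p <- pmin(pmax(1 / (1 + phi * gm), 1e-12), 1 - 1e-12)
  mu <- (1 - p) / (p * phi)
  hyper <- list(mu_beta = 0, s2_beta = 1,
                mu_phi = mean(log_phi),
                s2_phi = max(var(log_phi), 1e-2))
  atoms <- rnorm(K, hyper$mu_beta, sqrt(hyper$s2_beta))
  state <- list(
    t = matrix(1L, model$N, model$L),
    c = matrix(1L, model$L, K),
    z = matrix(1L, model$N, model$L),
    atoms = atoms,
    w = rep(1 / K, K),
    tw = matrix(1 / K, model$L, K),
    log_phi = log_phi, p = p, mu = mu,
    gamma = rep(1, model$L), delta = 1,
    hyper = hyper,
    tables = NULL,
    ## one adaptive proposal scale per atom and per gene ("per block")
    scales = list(atom = rep(config$atom_scale, K),
                  phi = rep(config$phi_scale, model$N)),
    accept = list(atom = NA_real_, phi = NA_real_),
    cache_ll = NULL,
    iteration = 0L,
    seed = config$seed)
  class(state) <- "chain_state"
  state
}

## ---- individual Gibbs updates (exported for testing / composability) ----

#' Blocked update of the table indicators
#'
#' Samples every `t[i, l]` from its exact categorical conditional
#' `p(t) proportional to tw[l, t] * prod_{j in group l}
#' NB(y_ij | c_j mu_i exp(atom[c[l, t]]), phi_i)`, using the pre-update
#' weights, maps and atoms for all cells simultaneously
#' (order-independent), then refreshes the derived indicator matrix
#' `z[i, l] = c[l, t[i, l]]`.
#'
#' @param state a `chain_state`.
#' @param model internal model bundle (see [run_chain()], which handles
#'   construction from `counts`, `groups`, `norm`).
#' @return the updated state.
#' @keywords internal
update_indicators <- function(state, model) {
  Tt <- ncol(state$c)
  lls <- atom_loglik(state, model)
  state$cache_ll <- lls   # consumed (and dropped) by update_weights
  u <- matrix(runif(model$N * model$L), model$N, model$L)
  lw <- log(pmax(state$tw, 1e-300))
  for (l in seq_len(model$L)) {
    logp <- lls[[l]][, state$c[l, ], drop = FALSE] +
      matrix(lw[l, ], model$N, Tt, byrow = TRUE)
    state$t[, l] <- cpp_sample_rows(logp, u[, l])
    state$z[, l] <- state$c[l, state$t[, l]]
  }
  state
}

rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  g <- pmax(g, 1e-300)
  g / sum(g)
}

#' Update weights and table-to-atom maps
#'
#' Per group: every occupied table is re-mapped to a global atom from the
#' blocked categorical `p(c[l, t] = k) proportional to
#' w_k * prod_{i in table t} lik(i, l, k)` (this is the move that merges
#' duplicate atoms across groups); unoccupied tables are prior draws from
#' `Categorical(w)`.  Table weights follow
#' `Dirichlet(gamma_l/T + table occupancy)` and the global weights
#' `Dirichlet(delta/K + atom usage counts over occupied tables)`.
#'
#' @inheritParams update_indicators
#' @return the updated state (with table/atom usage recorded in
#'   `state$tables` for the concentration updates).
#' @keywords internal
update_weights <- function(state, model) {
  K <- length(state$atoms); L <- model$L; Tt <- ncol(state$c)
  lls <- atom_loglik(state, model)
  lw <- log(pmax(state$w, 1e-300))
  n_tab <- matrix(0L, L, Tt)
  for (l in seq_len(L)) {
    n_tab[l, ] <- tabulate(state$t[, l], Tt)
    occ <- which(n_tab[l, ] > 0L)
    if (length(occ)) {
      ## column sums of the atom log-likelihood per occupied table
      S <- rowsum(lls[[l]], group = state$t[, l])
      S <- S[match(occ, as.integer(rownames(S))), , drop = FALSE]
      logp <- S + matrix(lw, length(occ), K, byrow = TRUE)
      state$c[l, occ] <- cpp_sample_rows(logp, runif(length(occ)))
    }
    un <- which(n_tab[l, ] == 0L)
    if (length(un))
      state$c[l, un] <- as.integer(
        sample.int(K, length(un), replace = TRUE, prob = state$w))
    state$tw[l, ] <- rdirichlet1(state$gamma[l] / Tt + n_tab[l, ])
    state$z[, l] <- state$c[l, state$t[, l]]
  }
  occ_ct <- state$c[n_tab > 0L]          # atoms used by occupied tables
  m <- tabulate(occ_ct, K)
  state$w <- rdirichlet1(state$delta / K + m)
  state$tables <- list(n_tab = n_tab, m = m)
  state$cache_ll <- NULL   # the cache never outlives the weights step
  state
}

#' Update the global fold-change atoms
#'
#' Unoccupied atoms are exact draws from the base measure
#' `Normal(mu_beta, sigma2_beta)`.  Each occupied atom takes one Gaussian
#' random-walk Metropolis step targeting the base-measure prior times the
#' negative binomial likelihood of every observation currently assigned to
#' it.  With `adapt = TRUE` the shared proposal scale moves toward ~30%
#' acceptance (burn-in only).
#'
#' @inheritParams update_indicators
#' @param adapt adapt the proposal scale after this sweep?
#' @return the updated state.
#' @keywords internal
update_atoms <- function(state, model, adapt = FALSE) {
  K <- length(state$atoms)
  state$cache_ll <- NULL
  cnt <- tabulate(state$z, K)
  occ <- which(cnt > 0L); unocc <- which(cnt == 0L)
  h <- state$hyper
  if (length(unocc))
    state$atoms[unocc] <- rnorm(length(unocc), h$mu_beta, sqrt(h$s2_beta))
  if (length(occ)) {
    sc <- rep_len(state$scales$atom, K)
    prop <- state$atoms
    prop[occ] <- prop[occ] + rnorm(length(occ), 0, sc[occ])
    phi <- exp(state$log_phi)
    bc <- matrix(state$atoms[state$z], model$N, model$L)
    bp <- matrix(prop[state$z], model$N, model$L)
    llc <- cpp_obs_loglik(model$y, phi, state$mu, model$cf, model$lambda,
                          model$L, bc)
    llp <- cpp_obs_loglik(model$y, phi, state$mu, model$cf, model$lambda,
                          model$L, bp)
    dll <- rowsum(as.vector(llp - llc), group = as.vector(state$z))
    dk <- setNames(dll[, 1], rownames(dll))[as.character(occ)]
    logr <- dk +
      dnorm(prop[occ], h$mu_beta, sqrt(h$s2_beta), log = TRUE) -
      dnorm(state$atoms[occ], h$mu_beta, sqrt(h$s2_beta), log = TRUE)
    acc <- log(runif(length(occ))) < logr
    state$atoms[occ[acc]] <- prop[occ[acc]]
    state$accept$atom <- mean(acc)
    if (adapt) {
      step <- min(0.25, 1 / sqrt(1 + state$iteration))
      sc[occ] <- sc[occ] * exp(step * (acc - 0.3))
      state$scales$atom <- sc
    }
  }
  state
}

#' Update the gene-level parameters (log phi_i, p_i)
#'
#' `log phi_i` by Gaussian random-walk Metropolis against its normal prior
#' times the full-data likelihood (the derived mean level moves with phi at
#' fixed p).  `p_i` by an independence Metropolis step whose proposal is
#' the conjugate `Beta(0.5 + M/phi_i, 0.5 + sum_j y_ij)`; when all
#' effective exposures `c_j * exp(beta)` are 1 the acceptance ratio is
#' identically 1 and the step is an exact conjugate draw.  The mean level
#' `mu_i` is recomputed deterministically afterwards.
#'
#' @inheritParams update_atoms
#' @return the updated state.
#' @keywords internal
update_gene_params <- function(state, model, adapt = FALSE) {
  state$cache_ll <- NULL
  beta_il <- matrix(state$atoms[state$z], model$N, model$L)
  phi <- exp(state$log_phi)

  ## --- dispersion step ---
  sc <- rep_len(state$scales$phi, model$N)
  lp_prop <- state$log_phi + rnorm(model$N, 0, sc)
  phi_prop <- exp(lp_prop)
  mu_prop <- (1 - state$p) / (state$p * phi_prop)
  llc <- rowSums(cpp_obs_loglik(model$y, phi, state$mu, model$cf,
                                model$lambda, model$L, beta_il))
  llp <- rowSums(cpp_obs_loglik(model$y, phi_prop, mu_prop, model$cf,
                                model$lambda, model$L, beta_il))
  h <- state$hyper
  logr <- (llp - llc) +
    dnorm(lp_prop, h$mu_phi, sqrt(h$s2_phi), log = TRUE) -
    dnorm(state$log_phi, h$mu_phi, sqrt(h$s2_phi), log = TRUE)
  acc <- log(runif(model$N)) < logr
  state$log_phi[acc] <- lp_prop[acc]
  phi <- exp(state$log_phi)
  state$mu <- (1 - state$p) / (state$p * phi)
  state$accept$phi <- mean(acc)
  if (adapt) {
    step <- min(0.25, 1 / sqrt(1 + state$iteration))
    state$scales$phi <- sc * exp(step * (acc - 0.3))
  }

  ## --- p step (independence MH with conjugate-style Beta proposal) ---
  r <- 1 / phi
  a <- 0.5 + model$M * r
  b <- 0.5 + rowSums(model$y)
  p_prop <- pmin(pmax(rbeta(model$N, a, b), 1e-12), 1 - 1e-12)
  mu_prop <- (1 - p_prop) / (p_prop * phi)
  llc <- rowSums(cpp_obs_loglik(model$y, phi, state$mu, model$cf,
                                model$lambda, model$L, beta_il))
  llp <- rowSums(cpp_obs_loglik(model$y, phi, mu_prop, model$cf,
                                model$lambda, model$L, beta_il))
  logr <- (llp - llc) +
    dbeta(p_prop, 0.5, 0.5, log = TRUE) -
    dbeta(state$p, 0.5, 0.5, log = TRUE) +
    dbeta(state$p, a, b, log = TRUE) -
    dbeta(p_prop, a, b, log = TRUE)
  acc <- log(runif(model$N)) < logr
  state$p[acc] <- p_prop[acc]
  state$mu <- (1 - state$p) / (state$p * phi)
  state
}

## Normal-Inverse-Gamma conditional draw given iid normal observations x.
nig_draw <- function(x, nig) {
  m0 <- nig[["m0"]]; k0 <- nig[["k0"]]; a0 <- nig[["a0"]]; b0 <- nig[["b0"]]
  n <- length(x)
  if (n == 0L) {
    s2 <- 1 / rgamma(1, shape = a0, rate = b0)
    return(c(mu = rnorm(1, m0, sqrt(s2 / k0)), s2 = s2))
  }
  xbar <- mean(x)
  ss <- sum((x - xbar)^2)
  kn <- k0 + n
  mn <- (k0 * m0 + n * xbar) / kn
  an <- a0 + n / 2
  bn <- b0 + ss / 2 + k0 * n * (xbar - m0)^2 / (2 * kn)
  s2 <- 1 / rgamma(1, shape = an, rate = bn)
  c(mu = rnorm(1, mn, sqrt(s2 / kn)), s2 = s2)
}

## Concentration update for the finite symmetric Dirichlet model: the
## weights are marginalised out, leaving the exact Dirichlet-multinomial
## likelihood of the occupancy counts,
##   p(counts | alpha) = Gamma(alpha)/Gamma(alpha + n) *
##                       prod_s Gamma(alpha/S + counts_s)/Gamma(alpha/S),
## combined with a Gamma(a, b) prior via one random-walk Metropolis step
## on log(alpha).  (The classic Escobar-West draw targets the infinite-DP
## marginal and is biased at finite truncation.)  With no data the draw
## falls back to the prior.
sample_concentration <- function(alpha, counts, a, b, scale = 0.7) {
  n <- sum(counts)
  if (n <= 0L) return(rgamma(1, shape = a, rate = b))
  S <- length(counts)
  lp <- function(x)   # log posterior in log(x) (includes the Jacobian)
    lgamma(x) - lgamma(x + n) +
      sum(lgamma(x / S + counts) - lgamma(x / S)) +
      a * log(x) - b * x
  prop <- alpha * exp(rnorm(1, 0, scale))
  if (log(runif(1)) < lp(prop) - lp(alpha)) prop else alpha
}

#' Update the hyperparameters
#'
#' `(mu_beta, sigma2_beta)` from the Normal-Inverse-Gamma conditional given
#' the occupied atoms (unoccupied atoms are marginalised out and refreshed
#' from the new base measure at the end of this update, which keeps the
#' conditional exact); `(mu_phi, sigma2_phi)` likewise given all
#' log-dispersions.  Each group concentration `gamma_l` and the global
#' `delta` take one Metropolis step on the exact finite-truncation
#' conditional (Dirichlet-multinomial likelihood of the table / atom-usage
#' occupancies with the weights marginalised out); the weights are then
#' refreshed under the new concentrations.
#'
#' @inheritParams update_indicators
#' @param nig,conc_shape,conc_rate hyperprior settings (see
#'   [sampler_config()]).
#' @return the updated state.
#' @keywords internal
update_hyperparams <- function(state, model, nig = c(m0 = 0, k0 = 0.01,
                                                     a0 = 2, b0 = 2),
                               conc_shape = 1, conc_rate = 1) {
  K <- length(state$atoms)
  cnt <- tabulate(state$z, K)
  occ <- which(cnt > 0L)
  d <- nig_draw(state$atoms[occ], nig)
  state$hyper$mu_beta <- d[["mu"]]; state$hyper$s2_beta <- d[["s2"]]
  d <- nig_draw(state$log_phi, nig)
  state$hyper$mu_phi <- d[["mu"]]; state$hyper$s2_phi <- d[["s2"]]
  if (!is.null(state$tables)) {
    for (l in seq_len(model$L))
      state$gamma[l] <- sample_concentration(state$gamma[l],
                                             state$tables$n_tab[l, ],
                                             conc_shape, conc_rate)
    state$delta <- sample_concentration(state$delta, state$tables$m,
                                        conc_shape, conc_rate)
    ## the weights were drawn under the old concentrations with the counts
    ## marginalised out of the concentration step; refresh them under the
    ## new values so no stale draw is consumed (partial collapse)
    Tt <- ncol(state$c)
    for (l in seq_len(model$L))
      state$tw[l, ] <- rdirichlet1(state$gamma[l] / Tt +
                                     state$tables$n_tab[l, ])
    state$w <- rdirichlet1(state$delta / K + state$tables$m)
  } else {
    for (l in seq_len(model$L))
      state$gamma[l] <- sample_concentration(state$gamma[l], integer(0),
                                             conc_shape, conc_rate)
    state$delta <- sample_concentration(state$delta, integer(0),
                                        conc_shape, conc_rate)
  }
  ## refresh unoccupied atoms from the new base measure (partial collapse)
  unocc <- which(cnt == 0L)
  if (length(unocc)) {
    state$atoms[unocc] <- rnorm(length(unocc), state$hyper$mu_beta,
                                sqrt(state$hyper$s2_beta))
    state$cache_ll <- NULL
  }
  state
}

## One full Gibbs sweep.
gibbs_sweep <- function(state, model, config, adapt) {
  state <- update_indicators(state, model)
  state <- update_weights(state, model)
  state <- update_atoms(state, model, adapt)
  state <- update_gene_params(state, model, adapt)
  update_hyperparams(state, model, config$nig,
                     config$conc_shape, config$conc_rate)
}

#' Run the blocked Gibbs sampler
#'
#' Performs `n_iter` full sweeps and returns the thinned post-burn-in
#' indicator samples (plus dispersion samples when configured).  The run is
#' fully reproducible from `config$seed`.  With a `store` directory the
#' chain is persisted ([write_chain()]) together with a plain-text progress
#' log of occupied-cluster counts, and a resumable checkpoint is written
#' every `checkpoint_every` sweeps.
#'
#' @inheritParams init_state
#' @param store optional directory for the chain store and checkpoints.
#' @param resume continue from the checkpoint found in `store`.
#' @param verbose print occupied-cluster counts every 100 sweeps.
#' @return an object of class `posterior_samples` with elements
#'   `z_samples` (list of N x L integer matrices), `phi_samples`
#'   (N x T matrix or NULL), `gene_ids`, `group_names`, `occupancy` (per-
#'   sweep occupied-cluster counts), `norm`, `config`, `final_state`.
#' @examples
#' sim <- generate_dataset(60, 2, frac_de = 0.2, seed = 1)
#' cfg <- sampler_config(trunc = 20, n_iter = 60, burn_in = 30, seed = 1)
#' ps <- run_chain(sim$counts, sim$groups, config = cfg)
#' length(ps$z_samples)  # (60 - 30) / 1 = 30 stored samples
#' @export
run_chain <- function(counts, groups, norm = NULL, config = sampler_config(),
                      store = NULL, resume = FALSE, verbose = FALSE) {
  model <- build_model(counts, groups, norm)
  if (is.null(norm)) norm <- size_factors(counts)
  ckpt <- if (!is.null(store)) file.path(store, "checkpoint.rds")
  if (!is.null(store) && !dir.exists(store))
    dir.create(store, recursive = TRUE)

  if (resume) {
    if (is.null(ckpt) || !file.exists(ckpt))
      stop("no checkpoint to resume from in ", if (is.null(store)) "<NULL>"
           else store)
    ck <- tryCatch(readRDS(ckpt),
                   error = function(e) stop("corrupt checkpoint: ",
                                            conditionMessage(e)))
    if (!all(c("state", "z_samples", "occupancy", "rng") %in% names(ck)))
      stop("corrupt checkpoint: missing fields")
    state <- ck$state; z_samples <- ck$z_samples
    phi_samples <- ck$phi_samples; occupancy <- ck$occupancy
    if (is.null(phi_samples)) phi_samples <- list()
    assign(".Random.seed", ck$rng, envir = globalenv())
  } else {
    state <- init_state(counts, groups, norm, config)
    z_samples <- list(); phi_samples <- list()
    occupancy <- integer(0)
  }

  K <- config$trunc
  warned_full <- FALSE
  for (iter in seq.int(state$iteration + 1L, config$n_iter)) {
    adapt <- iter <= config$burn_in
    state$iteration <- iter - 1L   # used by the adaptation step size
    state <- gibbs_sweep(state, model, config, adapt)
    state$iteration <- iter
    occupancy[iter] <- length(unique(as.vector(state$z)))
    ## atoms are exchangeable under the symmetric finite approximation, so
    ## a saturated dictionary is the analogue of occupying the last stick;
    ## the first sweeps start from uniform weights and transiently scatter
    ## indicators, so only post-burn-in saturation is diagnostic
    if (!warned_full && iter > config$burn_in && occupancy[iter] >= K) {
      warning("truncation level reached: all ", K, " atoms are occupied; ",
              "consider increasing trunc", call. = FALSE)
      warned_full <- TRUE
    }
    if (iter > config$burn_in &&
        (iter - config$burn_in) %% config$thin == 0L) {
      z_samples[[length(z_samples) + 1L]] <- state$z
      if (config$store_phi)
        phi_samples[[length(phi_samples) + 1L]] <- exp(state$log_phi)
    }
    if (verbose && iter %% 100L == 0L)
      message(sprintf("sweep %d: %d occupied clusters", iter,
                      occupancy[iter]))
    if (!is.null(store) && iter %% config$checkpoint_every == 0L &&
        iter < config$n_iter) {
      slim <- state; slim$cache_ll <- NULL
      saveRDS(list(state = slim, z_samples = z_samples,
                   phi_samples = phi_samples, occupancy = occupancy,
                   rng = get(".Random.seed", envir = globalenv())),
              ckpt)
    }
  }

  state$cache_ll <- NULL
  state$cache_atoms <- NULL
  ps <- structure(list(
    z_samples = z_samples,
    phi_samples = if (config$store_phi && length(phi_samples))
      do.call(cbind, phi_samples) else NULL,
    gene_ids = model$gene_ids,
    group_names = model$group_names,
    occupancy = occupancy,
    norm = as.numeric(norm),
    config = config,
    final_state = state), class = "posterior_samples")

  if (!is.null(store)) {
    write_chain(ps, store)
    if (file.exists(ckpt)) unlink(ckpt)
  }
  ps
}

#' @export
print.posterior_samples <- function(x, ...) {
  cat(sprintf(paste0("posterior_samples: %d stored indicator samples, ",
                     "%d genes, groups: %s\n"),
              length(x$z_samples), length(x$gene_ids),
              paste(x$group_names, collapse = ", ")))
  invisible(x)
}
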