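# Sampler unit tests.  Conditionals are checked against enumeration and
# closed forms; the joint is checked by a Geweke-style comparison of the
# forward simulator with Gibbs-plus-data-resimulation.

# Frozen state with the table-to-atom maps pinned to the identity, so the
# table indicators coincide with the atom indicators and conditionals can
# be enumerated directly.
frozen_state <- function(fix, K = 2, seed = 1,
                         atoms = NULL, tw = NULL, w = NULL,
                         phi = NULL, mu = NULL) {
  cfg <- sampler_config(trunc = K, n_iter = 2, burn_in = 1, seed = seed)
  st <- init_state(fix$counts, fix$groups, norm_factors(
    rep(1, length(fix$groups$group))), cfg)
  L <- fix$groups$n_groups
  st$c <- matrix(rep(seq_len(K), each = L), L, K)   # identity maps
  if (!is.null(atoms)) st$atoms <- atoms
  if (!is.null(tw)) st$tw <- tw
  if (!is.null(w)) st$w <- w
  if (!is.null(phi)) { st$log_phi <- log(phi) }
  if (!is.null(mu)) {
    st$mu <- mu
    st$p <- 1 / (1 + exp(st$log_phi) * mu)
  }
  st
}

test_that("init_state honours its shape and determinism contracts", {
  fix <- tiny_counts()
  cfg <- sampler_config(trunc = 4, n_iter = 10, burn_in = 2, seed = 42)
  a <- init_state(fix$counts, fix$groups, config = cfg)
  b <- init_state(fix$counts, fix$groups, config = cfg)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
  one <- tiny_counts(vals = c(3, 1, 0, 2), n_genes = 1,
                     lib_groups = c("A", "A", "B", "B"))
  st <- init_state(one$counts, one$groups, norm_factors(rep(1, 4)), cfg)
  expect_equal(dim(st$z), c(1L, 2L))
  expect_true(all(st$z == 1L))            # every gene starts in atom 1
  expect_length(st$w, 4)
  expect_equal(sum(st$w), 1, tolerance = 1e-12)
  expect_equal(rowSums(st$tw), rep(1, 2), tolerance = 1e-12)
  expect_equal(st$mu, mean_from_p(st$p, exp(st$log_phi)))
  zero <- tiny_counts(vals = c(0, 0, 0, 0, 5, 2, 3, 1), n_genes = 2)
  expect_error(init_state(zero$counts, zero$groups, config = cfg),
               "zero total count")
})

test_that("indicator updates sample the enumerated conditional", {
  # 2 genes, 2 single-library groups, 2 atoms, everything frozen
  fix <- tiny_counts(vals = c(4, 9, 15, 3), n_genes = 2,
                     lib_groups = c("A", "B"))
  model <- tiny_model(fix, norm_factors(c(1, 1)))
  st <- frozen_state(fix, K = 2,
                     atoms = c(0, log(3)),
                     tw = rbind(c(0.7, 0.3), c(0.4, 0.6)),
                     phi = c(0.2, 0.4), mu = c(5, 8))
  # brute-force conditional per (gene, group); with identity maps the
  # table indicator equals the atom indicator
  probs <- array(0, c(2, 2, 2))
  for (i in 1:2) for (l in 1:2) {
    lp <- sapply(1:2, function(k)
      log(st$tw[l, k]) +
        ref_nb(model$y[i, l], st$mu[i] * exp(st$atoms[k]),
               exp(st$log_phi[i])))
    probs[i, l, ] <- exp(lp - max(lp)) / sum(exp(lp - max(lp)))
  }
  set.seed(99)
  n <- 20000
  hits <- array(0L, c(2, 2, 2))
  for (t in seq_len(n)) {
    z <- update_indicators(st, model)$z
    for (i in 1:2) for (l in 1:2)
      hits[i, l, z[i, l]] <- hits[i, l, z[i, l]] + 1L
  }
  for (i in 1:2) for (l in 1:2) {
    pv <- chisq.test(hits[i, l, ], p = probs[i, l, ])$p.value
    expect_gt(pv, 0.01)
  }
})

test_that("K = 1 is the degenerate categorical and the kernel is row-local", {
  fix <- tiny_counts()
  model <- tiny_model(fix, norm_factors(rep(1, 4)))
  st <- frozen_state(fix, K = 2)
  st$atoms <- 0; st$w <- 1; st$tw <- matrix(1, 2, 1)
  st$c <- matrix(1L, 2, 1)
  st$t <- matrix(1L, 2, 2)
  st$z <- matrix(1L, 2, 2)
  set.seed(1)
  expect_true(all(update_indicators(st, model)$z == 1L))
  # the categorical kernel is independent across rows: permuting rows of
  # (logp, u) permutes the sampled indicators
  set.seed(2)
  logp <- matrix(rnorm(40), 8, 5)
  u <- runif(8)
  z <- countHDP:::cpp_sample_rows(logp, u)
  prm <- sample(8)
  expect_equal(countHDP:::cpp_sample_rows(logp[prm, ], u[prm]), z[prm])
})

test_that("weight/map updates match enumerated conditionals", {
  # Each of the 3 genes sits alone at its own table in both groups, so
  # table occupancies are deterministic and the means have closed forms:
  #   E tw[l, t] = (gamma_l/T + 1) / (gamma_l + 3)
  #   p(c[l, t] = k) prop. to w_k * exp(LL_l[t, k])   (enumerable)
  #   E w_k = (delta/K + E m_k) / (delta + 6),  m_k = atom usage counts
  fix <- tiny_counts(vals = c(5, 9, 2, 7, 40, 35, 80, 60, 3, 6, 2, 9),
                     n_genes = 3, lib_groups = c("A", "A", "B", "B"))
  model <- tiny_model(fix, norm_factors(rep(1, 4)))
  st <- frozen_state(fix, K = 3,
                     atoms = c(-0.7, 0, 0.9),
                     w = c(0.5, 0.3, 0.2),
                     phi = c(0.3, 0.2, 0.5), mu = c(6, 50, 5))
  st$t <- matrix(rep(1:3, 2), 3)
  st$z <- matrix(rep(1:3, 2), 3)   # identity maps
  st$gamma <- c(2, 0.5); st$delta <- 1.5
  K <- 3
  # enumerate the c conditional per (group, table=gene)
  cprob <- array(0, c(2, 3, K))
  for (l in 1:2) for (t in 1:3) {
    js <- which(model$lambda == l)
    lp <- sapply(1:K, function(k)
      log(st$w[k]) + sum(ref_nb(model$y[t, js],
                                st$mu[t] * exp(st$atoms[k]),
                                exp(st$log_phi[t]))))
    cprob[l, t, ] <- exp(lp - max(lp)) / sum(exp(lp - max(lp)))
  }
  Em <- sapply(1:K, function(k) sum(cprob[, , k]))
  Ew <- (st$delta / K + Em) / (st$delta + 6)
  set.seed(8)
  n <- 20000
  acc_w <- numeric(K); acc_tw <- matrix(0, 2, K)
  hits <- array(0, c(2, 3, K))
  for (rep in seq_len(n)) {
    s2 <- update_weights(st, model)   # st never mutated: draws are iid
    acc_w <- acc_w + s2$w
    acc_tw <- acc_tw + s2$tw
    for (l in 1:2) for (t in 1:3)
      hits[l, t, s2$c[l, t]] <- hits[l, t, s2$c[l, t]] + 1
  }
  for (l in 1:2) for (t in 1:3)
    expect_lt(max(abs(hits[l, t, ] / n - cprob[l, t, ])), 0.015)
  expect_lt(max(abs(acc_w / n - Ew)), 0.01)
  for (l in 1:2) {
    Etw <- (st$gamma[l] / K + 1) / (st$gamma[l] + 3)
    expect_lt(max(abs(acc_tw[l, ] / n - Etw)), 0.01)
  }
  # data-dominated limit: gamma -> 0 with all genes at table 1
  st$t <- matrix(1L, 3, 2)
  st$z <- matrix(1L, 3, 2)
  st$gamma <- c(1e-9, 1e-9)
  s2 <- update_weights(st, model)
  expect_gt(min(s2$tw[, 1]), 0.999)
})

test_that("map updates merge duplicate atoms across groups", {
  # group A sits on atom 1, group B on atom 2, with numerically equal
  # atom values: re-mapping whole tables must align the groups on a
  # common atom most of the time (the one-layer scheme cannot do this)
  set.seed(44)
  y <- matrix(rnbinom(200, mu = 50, size = 5), 50, 4)
  y[y == 0] <- 1
  fix <- tiny_counts(vals = as.vector(t(y)), n_genes = 50)
  model <- tiny_model(fix, norm_factors(rep(1, 4)))
  st <- frozen_state(fix, K = 6, atoms = c(0, 0 + 1e-9, rnorm(4)),
                     w = rep(1 / 6, 6), phi = rep(0.2, 50),
                     mu = rowMeans(y))
  st$t <- matrix(1L, 50, 2)
  st$c <- rbind(c(1L, 3L, 4L, 5L, 6L, 2L),
                c(2L, 3L, 4L, 5L, 6L, 1L))
  st$z <- matrix(rep(c(1L, 2L), each = 50), 50)   # split configuration
  agree <- replicate(400, {
    s2 <- update_weights(st, model)
    s2$c[1, 1] == s2$c[2, 1]
  })
  expect_gt(mean(agree), 0.4)   # ~1/2 under indifference; 0 when stuck
})

test_that("atom updates: prior draws, frozen proposals, MH target", {
  fix <- tiny_counts(vals = c(200, 150), n_genes = 1,
                     lib_groups = c("A", "B"))
  model <- tiny_model(fix, norm_factors(c(1, 1)))
  st <- frozen_state(fix, K = 4, phi = 0.1, mu = 150)
  st$z <- matrix(c(1L, 2L), 1)
  st$hyper$mu_beta <- 0.3; st$hyper$s2_beta <- 0.5
  st$tables <- NULL

  # zero proposal scale: never moves, yet always "accepts"
  st0 <- st; st0$scales$atom <- 0
  set.seed(4)
  out <- update_atoms(st0, model)
  expect_identical(out$atoms[1:2], st$atoms[1:2])
  expect_equal(out$accept$atom, 1)

  # unoccupied atoms are exact prior draws
  set.seed(5)
  un <- replicate(4000, update_atoms(st, model)$atoms[3])
  expect_lt(abs(mean(un) - 0.3), 4 * sqrt(0.5 / 4000))
  expect_lt(abs(var(un) - 0.5), 4 * sqrt(2 * 0.5^2 / 4000))

  # long-run MH histogram vs 1-D numerical integration of the true
  # conditional for atom 1 (single observation y = 200)
  dens <- function(b) exp(ref_nb(200, 150 * exp(b), 0.1) +
                            dnorm(b, 0.3, sqrt(0.5), log = TRUE))
  Z <- integrate(Vectorize(dens), -5, 5)$value
  m1 <- integrate(Vectorize(function(b) b * dens(b)), -5, 5)$value / Z
  m2 <- integrate(Vectorize(function(b) b^2 * dens(b)), -5, 5)$value / Z
  set.seed(6)
  cur <- st
  trace <- numeric(20000)
  for (t in seq_along(trace)) {
    cur <- update_atoms(cur, model)
    trace[t] <- cur$atoms[1]
  }
  expect_lt(abs(mean(trace) - m1), 0.03)
  expect_lt(abs(var(trace) - (m2 - m1^2)), 0.3 * (m2 - m1^2))
})

test_that("p step is the exact conjugate Beta draw at unit exposures", {
  fix <- tiny_counts(vals = c(6, 11, 3, 9), n_genes = 1,
                     lib_groups = c("A", "A", "B", "B"))
  model <- tiny_model(fix, norm_factors(rep(1, 4)))
  st <- frozen_state(fix, K = 3, phi = 0.5, mu = 7)
  st$atoms <- c(0, 0, 0)         # all exposures c_j * e^beta = 1
  st$z <- matrix(1L, 1, 2)
  st$scales$phi <- 0             # freeze the dispersion random walk
  r <- 1 / 0.5
  a <- 0.5 + 4 * r; b <- 0.5 + sum(model$y[1, ])
  set.seed(12)
  ps <- replicate(5000, update_gene_params(st, model)$p[1])  # iid draws
  expect_lt(abs(mean(ps) - a / (a + b)),
            4 * sd(ps) / sqrt(length(ps)))
  vb <- a * b / ((a + b)^2 * (a + b + 1))
  expect_lt(abs(var(ps) - vb), 4 * vb / sqrt(length(ps) / 8))
  # mu is recomputed exactly from (p, phi) after every update
  set.seed(13)
  out <- update_gene_params(st, model)
  expect_equal(out$mu, mean_from_p(out$p, exp(out$log_phi)))
})

test_that("hyperparameter draws match the Normal-Inverse-Gamma oracle", {
  fix <- tiny_counts(vals = rep(c(5, 9, 2, 7), 5), n_genes = 5,
                     lib_groups = c("A", "A", "B", "B"))
  model <- tiny_model(fix, norm_factors(rep(1, 4)))
  st <- frozen_state(fix, K = 8)
  x <- c(-1.2, -0.3, 0.1, 0.8, 2.0)   # the five occupied atoms
  st$atoms[1:5] <- x
  st$z <- matrix(rep(1:5, 2), 5)
  st$tables <- NULL
  nig <- c(m0 = 0, k0 = 0.01, a0 = 3, b0 = 2)
  n <- length(x); xb <- mean(x)
  kn <- nig["k0"] + n
  mn <- (nig["k0"] * nig["m0"] + n * xb) / kn
  an <- nig["a0"] + n / 2
  bn <- nig["b0"] + sum((x - xb)^2) / 2 +
    nig["k0"] * n * (xb - nig["m0"])^2 / (2 * kn)
  Es2 <- bn / (an - 1)
  Vs2 <- bn^2 / ((an - 1)^2 * (an - 2))
  Vmu <- bn / (kn * (an - 1))          # marginal t variance of mu
  set.seed(14)
  draws <- replicate(20000, {
    s <- update_hyperparams(st, model, nig = nig)
    c(s$hyper$mu_beta, s$hyper$s2_beta)
  })
  expect_lt(abs(mean(draws[1, ]) - mn), 4 * sqrt(Vmu / 20000))
  expect_lt(abs(mean(draws[2, ]) - Es2), 4 * sqrt(Vs2 / 20000))
  expect_lt(abs(var(draws[1, ]) - Vmu), 0.15 * Vmu)
  # with no table counts the concentrations are pure prior draws
  set.seed(15)
  g <- replicate(5000, update_hyperparams(st, model, nig = nig,
                                          conc_shape = 1,
                                          conc_rate = 1)$delta)
  expect_lt(abs(mean(g) - 1), 4 / sqrt(5000))
  expect_lt(abs(var(g) - 1), 0.15)
})

test_that("concentration MH targets the Dirichlet-multinomial posterior", {
  counts <- c(5L, 2L, 1L, 0L, 0L, 0L)   # occupancies over 6 slots
  n <- sum(counts); S <- length(counts)
  post <- function(x)   # unnormalised posterior density in x
    exp(lgamma(x) - lgamma(x + n) +
          sum(lgamma(x / S + counts) - lgamma(x / S))) * dgamma(x, 1, 1)
  Z <- integrate(Vectorize(post), 0, 60)$value
  m1 <- integrate(Vectorize(function(x) x * post(x)), 0, 60)$value / Z
  set.seed(19)
  a <- 1; trace <- numeric(30000)
  for (i in seq_along(trace)) {
    a <- countHDP:::sample_concentration(a, counts, 1, 1)
    trace[i] <- a
  }
  expect_lt(abs(mean(trace) - m1), 0.05 * m1 + 0.02)
  # no data -> pure Gamma(a, b) prior draw
  set.seed(20)
  g <- replicate(4000, countHDP:::sample_concentration(3, integer(0), 2, 4))
  expect_lt(abs(mean(g) - 0.5), 4 * sqrt(2 / 16 / 4000))
})

test_that("run_chain: sample counting, determinism, resume, store", {
  fix <- tiny_counts(vals = c(5, 9, 2, 7, 40, 35, 80, 60, 13, 11, 2, 4),
                     n_genes = 3)
  cfg <- sampler_config(trunc = 6, n_iter = 10, burn_in = 5, seed = 7)
  ps <- run_chain(fix$counts, fix$groups, config = cfg)
  expect_length(ps$z_samples, 5)
  cfg2 <- sampler_config(trunc = 6, n_iter = 11, burn_in = 5, thin = 2,
                         seed = 7)
  expect_length(run_chain(fix$counts, fix$groups, config = cfg2)$z_samples,
                3)

  # identical seed => identical samples and byte-identical store
  d1 <- tempfile(); d2 <- tempfile()
  a <- run_chain(fix$counts, fix$groups, config = cfg, store = d1)
  b <- run_chain(fix$counts, fix$groups, config = cfg, store = d2)
  expect_identical(serialize(a$z_samples, NULL),
                   serialize(b$z_samples, NULL))
  for (f in c("chain.rds", "progress.log", "config.json"))
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))

  # resuming from a mid-run checkpoint reproduces the full run
  model <- tiny_model(fix)
  st <- init_state(fix$counts, fix$groups, size_factors(fix$counts), cfg)
  half <- list()
  for (it in 1:5) {
    st$iteration <- it - 1L
    st <- countHDP:::gibbs_sweep(st, model, cfg, adapt = it <= cfg$burn_in)
    st$iteration <- it
  }
  d3 <- tempfile(); dir.create(d3)
  saveRDS(list(state = st, z_samples = list(), phi_samples = list(),
               occupancy = rep(NA_integer_, 5),
               rng = get(".Random.seed", envir = globalenv())),
          file.path(d3, "checkpoint.rds"))
  res <- run_chain(fix$counts, fix$groups, config = cfg, store = d3,
                   resume = TRUE)
  expect_identical(serialize(res$z_samples, NULL),
                   serialize(a$z_samples, NULL))
  expect_false(file.exists(file.path(d3, "checkpoint.rds")))

  # corrupt checkpoint is reported, missing store is an error
  d4 <- tempfile(); dir.create(d4)
  saveRDS(list(oops = 1), file.path(d4, "checkpoint.rds"))
  expect_error(run_chain(fix$counts, fix$groups, config = cfg, store = d4,
                         resume = TRUE), "corrupt checkpoint")
  expect_error(read_chain(tempfile()), "no chain store")
  unlink(c(d1, d2, d3, d4), recursive = TRUE)
})

test_that("the joint distribution passes a Geweke-style check", {
  # tiny instance: N=4 genes, 2+2 libraries, K=4; compare the successive-
  # conditional sampler (Gibbs sweep + data resimulation) against analytic
  # prior moments and a forward-simulation oracle.
  N <- 4; K <- 4; L <- 2
  lambda <- c(1L, 1L, 2L, 2L); cf <- rep(1, 4)
  cfg <- sampler_config(trunc = K, n_iter = 2, burn_in = 1, seed = 1,
                        nig = c(m0 = 0, k0 = 1, a0 = 3, b0 = 2),
                        atom_scale = 0.4, phi_scale = 0.4)
  draw_params <- function() {
    s2b <- 1 / rgamma(1, 3, rate = 2)
    mub <- rnorm(1, 0, sqrt(s2b / 1))
    s2p <- 1 / rgamma(1, 3, rate = 2)
    mup <- rnorm(1, 0, sqrt(s2p / 1))
    gamma <- rgamma(L, 1, 1); delta <- rgamma(1, 1, 1)
    w <- as.numeric(countHDP:::rdirichlet1(rep(delta / K, K)))
    cc <- matrix(sample.int(K, L * K, replace = TRUE, prob = w), L, K)
    tw <- t(sapply(seq_len(L),
                   function(l) countHDP:::rdirichlet1(rep(gamma[l] / K,
                                                          K))))
    tt <- matrix(0L, N, L); z <- matrix(0L, N, L)
    for (l in seq_len(L)) {
      tt[, l] <- sample.int(K, N, replace = TRUE, prob = tw[l, ])
      z[, l] <- cc[l, tt[, l]]
    }
    atoms <- rnorm(K, mub, sqrt(s2b))
    log_phi <- rnorm(N, mup, sqrt(s2p))
    p <- pmin(pmax(rbeta(N, 0.5, 0.5), 1e-12), 1 - 1e-12)
    list(t = tt, c = cc, z = z, atoms = atoms, w = w, tw = tw,
         log_phi = log_phi, p = p,
         mu = (1 - p) / (p * exp(log_phi)), gamma = gamma, delta = delta,
         hyper = list(mu_beta = mub, s2_beta = s2b, mu_phi = mup,
                      s2_phi = s2p),
         tables = NULL, scales = list(atom = 0.4, phi = 0.4),
         accept = list(atom = NA_real_, phi = NA_real_),
         cache_ll = NULL, iteration = 0L)
  }
  simulate_y <- function(st) {
    y <- matrix(0, N, 4)
    for (j in 1:4) {
      m <- cf[j] * st$mu * exp(st$atoms[st$z[, lambda[j]]])
      y[, j] <- rnbinom(N, mu = pmin(m, 1e7), size = exp(-st$log_phi))
    }
    y
  }
  stat <- function(st) c(inv_s2 = 1 / st$hyper$s2_beta,
                         zscore = st$hyper$mu_beta /
                           sqrt(st$hyper$s2_beta),
                         occ = length(unique(as.vector(st$z))))
  set.seed(101)
  n_s <- 6000
  st <- draw_params(); class(st) <- "chain_state"
  y <- simulate_y(st)
  succ <- matrix(0, n_s, 3)
  for (t in seq_len(n_s)) {
    model <- list(y = y, N = N, M = 4, L = L, lambda = lambda, cf = cf,
                  group_names = c("A", "B"), gene_ids = paste0("g", 1:N))
    st <- countHDP:::gibbs_sweep(st, model, cfg, adapt = FALSE)
    y <- simulate_y(st)
    succ[t, ] <- stat(st)
  }
  fwd_occ <- replicate(4000, {
    s <- draw_params()
    length(unique(as.vector(s$z)))
  })
  batch_se <- function(x, nb = 40) {
    bm <- colMeans(matrix(x[seq_len(nb * (length(x) %/% nb))],
                          ncol = nb))
    sd(bm) / sqrt(nb)
  }
  # analytic prior moments: E[1/s2] = a0/b0 = 1.5; mu/sqrt(s2) ~ N(0,1)
  z1 <- (mean(succ[, 1]) - 1.5) / batch_se(succ[, 1])
  z2 <- (mean(succ[, 2]) - 0) / batch_se(succ[, 2])
  z3 <- (mean(succ[, 3]) - mean(fwd_occ)) /
    sqrt(batch_se(succ[, 3])^2 + var(fwd_occ) / length(fwd_occ))
  expect_lt(abs(z1), 5)
  expect_lt(abs(z2), 5)
  expect_lt(abs(z3), 5)
})
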