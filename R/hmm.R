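# Variational-Bayes hidden Markov model for single-particle tracking.
#
# Emission model: given hidden diffusive state k, each displacement between
# successive frames has independent Gaussian x and y components with variance
# s_k = 2 * D_k * dt. Conjugate variational families: inverse-gamma q(s_k),
# Dirichlet q(A_k.) per transition row and Dirichlet q(pi). The evidence
# lower bound is the scaled forward-pass likelihood under the geometrically
# tilted parameters minus the KL of each factor from its prior, so it is
# non-decreasing across iterations.

#' Displacement sequences from a trajectory table
#'
#' Differences between successive positions, split wherever the frame index
#' jumps by more than one; trajectories with fewer than two positions are
#' dropped (counted in `n_dropped`).
#'
#' @param traj tibble with `traj_id`, `frame`, `x_um`, `y_um` (aliases `x`,
#'   `y` accepted).
#' @param dt_s frame interval in seconds (default 0.020 = 50 Hz).
#' @return object of class `displacement_set`: `steps` tibble (`seq`, `dx`,
#'   `dy`, `r2` in um / um^2), per-sequence lengths, `dt_s`, `n_dropped`.
#' @export
displacements <- function(traj, dt_s = 0.020) {
  check_number(dt_s, "dt_s", lower = 1e-12)
  traj <- as_tibble(traj)
  nm <- names(traj)
  nm[nm == "x"] <- "x_um"; nm[nm == "y"] <- "y_um"
  names(traj) <- nm
  if (!all(c("traj_id", "frame", "x_um", "y_um") %in% names(traj))) {
    abort("trajectory table needs columns `traj_id`, `frame`, `x_um`, `y_um`.")
  }
  traj <- arrange(traj, .data$traj_id, .data$frame)
  n_dropped <- 0L

  # split at frame gaps: new sequence whenever traj changes or frame jump > 1
  new_traj <- c(TRUE, traj$traj_id[-1] != traj$traj_id[-nrow(traj)])
  gap <- c(TRUE, diff(traj$frame) != 1L) | new_traj
  seg <- cumsum(gap)
  seg_len <- tabulate(seg)
  n_dropped <- sum(seg_len < 2)
  keep <- seg_len[seg] >= 2
  traj <- traj[keep, ]; seg <- seg[keep]
  if (nrow(traj) == 0) {
    steps <- tibble(seq = integer(), dx = numeric(), dy = numeric(), r2 = numeric())
    return(structure(list(steps = steps, seq_len = integer(), dt_s = dt_s,
                          n_dropped = n_dropped), class = "displacement_set"))
  }
  seg <- match(seg, unique(seg))
  last_of_seg <- c(seg[-1] != seg[-length(seg)], TRUE)
  dx <- c(diff(traj$x_um), 0)[!last_of_seg]
  dy <- c(diff(traj$y_um), 0)[!last_of_seg]
  steps <- tibble(seq = seg[!last_of_seg], dx = dx, dy = dy, r2 = dx^2 + dy^2)
  structure(
    list(steps = steps, seq_len = as.integer(table(steps$seq)), dt_s = dt_s,
         n_dropped = n_dropped),
    class = "displacement_set"
  )
}

#' @export
print.displacement_set <- function(x, ...) {
  cat(sprintf("<displacement_set> %d sequences, %d displacements, dt = %g s (%d dropped)\n",
              length(x$seq_len), nrow(x$steps), x$dt_s, x$n_dropped))
  invisible(x)
}

#' Priors for the diffusion HMM
#'
#' Weakly informative conjugate priors centred on a diffusion coefficient of
#' 0.1 um^2/s and a mean dwell of 50 frames (1000 ms at 20 ms/frame): the
#' inverse-gamma prior on the per-state emission variance `2*D*dt` carries
#' `strength_D` pseudo-observations at `prior_D_um2_s`, and each Dirichlet
#' transition row carries `prior_dwell_frames - 1` self-transition
#' pseudocounts with a total off-diagonal pseudocount of 1 split evenly.
#'
#' @param prior_D_um2_s prior diffusion coefficient (um^2/s).
#' @param prior_dwell_frames prior mean dwell in frames.
#' @param strength_D pseudo-observation weight of the D prior.
#' @return list of class `hmm_priors`.
#' @export
hmm_priors <- function(prior_D_um2_s = 0.1, prior_dwell_frames = 50,
                       strength_D = 1) {
  check_number(prior_D_um2_s, "prior_D_um2_s", lower = 1e-12)
  check_number(prior_dwell_frames, "prior_dwell_frames", lower = 1 + 1e-9)
  check_number(strength_D, "strength_D", lower = 1e-9)
  structure(list(prior_D_um2_s = prior_D_um2_s,
                 prior_dwell_frames = prior_dwell_frames,
                 strength_D = strength_D),
            class = "hmm_priors")
}

kl_dirichlet <- function(a, a0) {
  sum(lgamma(sum(a)) - sum(lgamma(a)) - lgamma(sum(a0)) + sum(lgamma(a0)) +
        sum((a - a0) * (digamma(a) - digamma(sum(a)))))
}

kl_invgamma <- function(a, b, a0, b0) {
  (a - a0) * digamma(a) - lgamma(a) + lgamma(a0) +
    a0 * (log(b) - log(b0)) + a * (b0 - b) / b
}

# index matrix (n_seq x max_len) of step row numbers, NA-padded
step_index_matrix <- function(seq_len_vec) {
  n_seq <- length(seq_len_vec)
  max_len <- max(seq_len_vec)
  idx <- matrix(NA_integer_, n_seq, max_len)
  starts <- cumsum(c(1L, head(seq_len_vec, -1L)))
  for (t in seq_len(max_len)) {
    act <- seq_len_vec >= t
    idx[act, t] <- starts[act] + t - 1L
  }
  idx
}

# One E-step: scaled forward-backward under tilted parameters.
# Returns sufficient statistics and the data part of the ELBO.
vb_estep <- function(r2, idx, lpi_t, lA_t, Elog_s, Einv_s) {
  K <- length(Elog_s)
  n_seq <- nrow(idx); Tm <- ncol(idx)
  # log emission for every step x state
  le <- matrix(-log(2 * pi), nrow = length(r2), ncol = K)
  le <- le - matrix(Elog_s, length(r2), K, byrow = TRUE) -
    outer(r2 / 2, Einv_s)
  Astar <- exp(lA_t)

  alpha <- array(NA_real_, c(n_seq, K, Tm))
  logc <- matrix(0, n_seq, Tm)
  shift <- matrix(0, n_seq, Tm)

  emis <- function(t) {
    rows <- idx[, t]
    act <- !is.na(rows)
    lem <- le[rows[act], , drop = FALSE]
    m <- lem[, 1]
    if (ncol(lem) > 1) for (k in 2:ncol(lem)) m <- pmax(m, lem[, k])
    list(e = exp(lem - m), m = m, act = act)
  }

  E1 <- emis(1)
  a <- E1$e * matrix(exp(lpi_t), sum(E1$act), K, byrow = TRUE)
  c1 <- rowSums(a)
  alpha[E1$act, , 1] <- a / c1
  logc[E1$act, 1] <- log(c1) + E1$m
  e_list <- vector("list", Tm); e_list[[1]] <- E1
  if (Tm > 1) {
    for (t in 2:Tm) {
      Et <- emis(t)
      if (!any(Et$act)) break
      prev <- alpha[Et$act, , t - 1, drop = FALSE]
      dim(prev) <- c(sum(Et$act), K)
      a <- (prev %*% Astar) * Et$e
      ct <- rowSums(a)
      alpha[Et$act, , t] <- a / ct
      logc[Et$act, t] <- log(ct) + Et$m
      e_list[[t]] <- Et
    }
  }

  # backward with accumulation
  Nk <- numeric(K); Sk <- numeric(K)
  xi <- matrix(0, K, K)
  gamma1 <- numeric(K)
  beta <- matrix(1, n_seq, K)
  for (t in Tm:1) {
    Et <- e_list[[t]]
    if (is.null(Et)) next
    act <- Et$act
    al <- alpha[act, , t, drop = FALSE]; dim(al) <- c(sum(act), K)
    bt <- beta[act, , drop = FALSE]
    g <- al * bt
    g <- g / rowSums(g)
    rows <- idx[act, t]
    Nk <- Nk + colSums(g)
    Sk <- Sk + colSums(g * r2[rows])
    if (t == 1) gamma1 <- colSums(g)   # every sequence is active at t = 1
    if (t > 1) {
      # xi over (t-1 -> t) for sequences active at t
      alm1 <- alpha[act, , t - 1, drop = FALSE]; dim(alm1) <- c(sum(act), K)
      ct <- exp(logc[act, t] - Et$m)
      xi <- xi + Astar * (t(alm1) %*% (Et$e * bt / ct))
      # propagate beta to t-1 over active sequences
      beta[act, ] <- ((Et$e * bt) %*% t(Astar)) / ct
    }
  }
  list(Nk = Nk, Sk = Sk, xi = xi, gamma1 = gamma1,
       loglik = sum(logc), n_steps = length(r2))
}

vb_mstep <- function(stats, prior, K, s0) {
  a0 <- prior$strength_D / 2
  b0 <- a0 * s0
  a_s <- a0 + stats$Nk
  b_s <- b0 + stats$Sk / 2
  if (K == 1L) {
    return(list(a_s = a_s, b_s = b_s, alpha_A = matrix(1, 1, 1),
                beta_pi = 1, a0 = a0, b0 = b0))
  }
  diag0 <- prior$prior_dwell_frames - 1
  off0 <- 1 / (K - 1)
  A0 <- matrix(off0, K, K); diag(A0) <- diag0
  pi0 <- rep(1, K)
  list(a_s = a_s, b_s = b_s,
       alpha_A = A0 + stats$xi,
       beta_pi = pi0 + stats$gamma1,
       A0 = A0, pi0 = pi0, a0 = a0, b0 = b0)
}

vb_tilted <- function(par, K) {
  Elog_s <- log(par$b_s) - digamma(par$a_s)
  Einv_s <- par$a_s / par$b_s
  if (K == 1L) {
    lA_t <- matrix(0, 1, 1); lpi_t <- 0
  } else {
    lA_t <- digamma(par$alpha_A) - digamma(rowSums(par$alpha_A))
    lpi_t <- digamma(par$beta_pi) - digamma(sum(par$beta_pi))
  }
  list(Elog_s = Elog_s, Einv_s = Einv_s, lA_t = lA_t, lpi_t = lpi_t)
}

vb_kl <- function(par, K) {
  kl <- sum(kl_invgamma(par$a_s, par$b_s, par$a0, par$b0))
  if (K > 1L) {
    for (k in seq_len(K)) kl <- kl + kl_dirichlet(par$alpha_A[k, ], par$A0[k, ])
    kl <- kl + kl_dirichlet(par$beta_pi, par$pi0)
  }
  kl
}

# random hard initialisation of responsibilities from a k-means split of r2
vb_init_stats <- function(r2, idx, K, seq_of_step) {
  n <- length(r2)
  if (K == 1L) {
    lab <- rep(1L, n)
  } else {
    v <- log(r2 + 1e-12)
    centers <- sort(sample(v, K)) + rnorm(K, 0, 0.1)
    km <- tryCatch(stats::kmeans(v, centers = matrix(centers, ncol = 1), iter.max = 20),
                   error = function(e) NULL)
    lab <- if (is.null(km)) sample.int(K, n, replace = TRUE) else km$cluster
    # rank labels by centre so state 1 starts as the slow state
    if (!is.null(km)) lab <- rank(km$centers[, 1], ties.method = "first")[lab]
  }
  g <- matrix(0, n, K); g[cbind(seq_len(n), lab)] <- 1
  Nk <- colSums(g)
  Sk <- colSums(g * r2)
  first <- idx[, 1]
  gamma1 <- colSums(g[first[!is.na(first)], , drop = FALSE])
  # transition counts from consecutive hard labels within sequences
  xi <- matrix(1e-3, K, K)
  same <- seq_of_step[-1] == seq_of_step[-n]
  if (n > 1 && any(same)) {
    from <- lab[-n][same]; to <- lab[-1][same]
    for (k in seq_len(K)) {
      if (any(from == k)) xi[k, ] <- xi[k, ] + tabulate(to[from == k], K)
    }
  }
  list(Nk = Nk, Sk = Sk, xi = xi, gamma1 = gamma1)
}

#' Fit a K-state diffusion HMM by variational Bayes
#'
#' Pooled over all displacement sequences. Each iteration alternates a scaled
#' forward-backward E-step under the tilted (geometric-mean) parameters with
#' conjugate parameter updates; the evidence lower bound (ELBO, nats) is
#' non-decreasing and iteration stops when its gain per displacement drops
#' below `tol`. Restarts differ in their randomised initial responsibilities;
#' each restart is run `warm_iter` iterations and the best bound is continued
#' to convergence. States are returned sorted by diffusion coefficient.
#'
#' @param ds a `displacement_set` from [displacements()].
#' @param K number of diffusive states (1, 2 or 3).
#' @param priors an [hmm_priors()] object.
#' @param n_restarts random restarts (default 10).
#' @param max_iter iteration cap (default 500).
#' @param tol ELBO gain per displacement below which iteration stops.
#' @param warm_iter iterations given to each restart before the best is
#'   continued.
#' @param seed integer seed for the restart initialisations.
#' @return object of class `diffusion_hmm` with elements `K`, `D_um2_s`
#'   (ascending), `A` (posterior-mean transition matrix), `pi`, `occupancy`
#'   (posterior mass per state), `evidence` (final ELBO), `elbo_trace`,
#'   `converged`, `n_iter`, `dt_s`, `D_floored`.
#' @export
fit_hmm <- function(ds, K, priors = hmm_priors(), n_restarts = 10,
                    max_iter = 500, tol = 1e-6, warm_iter = 25, seed = NULL) {
  stopifnot(inherits(ds, "displacement_set"))
  if (!K %in% 1:3) abort("`K` must be 1, 2 or 3.")
  check_number(tol, "tol", lower = 1e-15)
  check_number(n_restarts, "n_restarts", lower = 1, integerish = TRUE)
  if (nrow(ds$steps) == 0) abort("no displacements to fit.")
  local_seed_if(seed)

  r2 <- ds$steps$r2
  idx <- step_index_matrix(ds$seq_len)
  seq_of_step <- ds$steps$seq
  s0 <- 2 * priors$prior_D_um2_s * ds$dt_s
  n <- length(r2)

  run <- function(stats, iters, trace0 = numeric(0)) {
    trace <- trace0
    par <- vb_mstep(stats, priors, K, s0)
    converged <- FALSE
    it <- 0L
    est <- NULL
    while (it < iters) {
      it <- it + 1L
      tilt <- vb_tilted(par, K)
      est <- vb_estep(r2, idx, tilt$lpi_t, tilt$lA_t, tilt$Elog_s, tilt$Einv_s)
      elbo <- est$loglik - vb_kl(par, K)
      trace <- c(trace, elbo)
      m <- length(trace)
      if (m > 1 && (trace[m] - trace[m - 1]) < tol * n) {
        converged <- TRUE
        par <- vb_mstep(est, priors, K, s0)
        break
      }
      par <- vb_mstep(est, priors, K, s0)
    }
    list(par = par, est = est, trace = trace, converged = converged)
  }

  best <- NULL
  n_restarts_eff <- if (K == 1L) 1L else n_restarts
  for (rs in seq_len(n_restarts_eff)) {
    st <- vb_init_stats(r2, idx, K, seq_of_step)
    res <- run(st, warm_iter)
    if (is.null(best) || tail(res$trace, 1) > tail(best$trace, 1)) best <- res
  }
  if (!best$converged) {
    res <- run(best$est, max(1L, max_iter - length(best$trace)),
               trace0 = best$trace)
    best <- res
  }

  par <- best$par
  a_s <- par$a_s; b_s <- par$b_s
  Es <- ifelse(a_s > 1, b_s / (a_s - 1), b_s / a_s)
  D <- Es / (2 * ds$dt_s)
  D_floor <- 1e-12
  D_floored <- D < D_floor
  D <- pmax(D, D_floor)
  occ <- best$est$Nk / sum(best$est$Nk)
  if (K == 1L) {
    A <- matrix(1, 1, 1); pi_hat <- 1
  } else {
    A <- par$alpha_A / rowSums(par$alpha_A)
    pi_hat <- par$beta_pi / sum(par$beta_pi)
  }

  ord <- order(D)
  structure(
    list(K = as.integer(K),
         D_um2_s = D[ord],
         A = A[ord, ord, drop = FALSE],
         pi = pi_hat[ord],
         occupancy = occ[ord],
         evidence = tail(best$trace, 1),
         elbo_trace = best$trace,
         converged = best$converged,
         n_iter = length(best$trace),
         n_displacements = n,
         dt_s = ds$dt_s,
         D_floored = D_floored[ord],
         priors = priors),
    class = "diffusion_hmm"
  )
}

#' @export
print.diffusion_hmm <- function(x, ...) {
  cat(sprintf("<diffusion_hmm> K = %d, ELBO = %.2f (%s, %d iterations)\n",
              x$K, x$evidence, if (x$converged) "converged" else "not converged",
              x$n_iter))
  print(tidy(x))
  invisible(x)
}

#' @rdname fit_hmm
#' @param x a `diffusion_hmm` object.
#' @param ... unused.
#' @method tidy diffusion_hmm
#' @export
tidy.diffusion_hmm <- function(x, ...) {
  tibble(state = seq_len(x$K),
         D_um2_s = x$D_um2_s,
         self_transition = diag(x$A),
         dwell_time_ms = 1000 * x$dt_s / pmax(1 - diag(x$A), .Machine$double.eps),
         occupancy = x$occupancy)
}

#' @rdname fit_hmm
#' @method glance diffusion_hmm
#' @export
glance.diffusion_hmm <- function(x, ...) {
  tibble(K = x$K, evidence = x$evidence, converged = x$converged,
         n_iter = x$n_iter, n_displacements = x$n_displacements)
}

#' Choose the number of diffusive states by maximal evidence
#'
#' Fits every candidate K and returns the model with the highest evidence
#' lower bound; ties within 0.1 nat are broken toward the smaller
#' (more parsimonious) K.
#'
#' @inheritParams fit_hmm
#' @param candidate_K non-empty subset of 1:3.
#' @return object of class `hmm_selection`: `best` (a `diffusion_hmm`),
#'   `bounds` tibble (`K`, `evidence`, `converged`), `best_K`.
#' @export
select_model <- function(ds, priors = hmm_priors(), candidate_K = 1:3,
                         n_restarts = 10, max_iter = 500, tol = 1e-6,
                         warm_iter = 25, seed = NULL) {
  if (length(candidate_K) == 0 || !all(candidate_K %in% 1:3)) {
    abort("`candidate_K` must be a non-empty subset of 1:3.")
  }
  local_seed_if(seed)
  fits <- lapply(sort(unique(candidate_K)), function(K) {
    fit_hmm(ds, K, priors = priors, n_restarts = n_restarts,
            max_iter = max_iter, tol = tol, warm_iter = warm_iter)
  })
  bounds <- tibble(
    K = vapply(fits, function(f) f$K, integer(1)),
    evidence = vapply(fits, function(f) f$evidence, numeric(1)),
    converged = vapply(fits, function(f) f$converged, logical(1))
  )
  # parsimony tie-break: smallest K within 0.1 nat of the maximum
  best_i <- which(bounds$evidence >= max(bounds$evidence) - 0.1)[1]
  structure(list(best = fits[[best_i]], bounds = bounds,
                 best_K = bounds$K[best_i]),
            class = "hmm_selection")
}

#' @export
print.hmm_selection <- function(x, ...) {
  cat(sprintf("<hmm_selection> best K = %d\n", x$best_K))
  print(x$bounds)
  invisible(x)
}

#' @rdname select_model
#' @param x an `hmm_selection` object.
#' @param ... unused.
#' @method glance hmm_selection
#' @export
glance.hmm_selection <- function(x, ...) x$bounds

#' Per-state diffusion metrics
#'
#' The per-state readouts: diffusion coefficient, mean dwell time
#' `1000 * dt / (1 - A_kk)` in ms, occupancy as posterior probability mass
#' over all displacement steps, and the stationary occupancy implied by the
#' transition matrix. States with `A_kk = 1` get infinite dwell and are
#' flagged.
#'
#' @param m a `diffusion_hmm`.
#' @return tibble with `state`, `D_um2_s`, `dwell_time_ms`, `dwell_infinite`,
#'   `occupancy`, `occupancy_stationary`.
#' @export
state_metrics <- function(m) {
  stopifnot(inherits(m, "diffusion_hmm"))
  akk <- diag(m$A)
  inf_dwell <- akk >= 1 - 1e-12
  dwell <- ifelse(inf_dwell, Inf, 1000 * m$dt_s / (1 - akk))
  tibble(
    state = seq_len(m$K),
    D_um2_s = m$D_um2_s,
    dwell_time_ms = dwell,
    dwell_infinite = inf_dwell,
    occupancy = m$occupancy,
    occupancy_stationary = stationary_distribution(m$A)
  )
}
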