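## Internal coordinate-ascent machinery for the variational Bayesian ICA
## mixture model.
##
## Generative model, per cluster k (all in standardized data space):
##   y_n | c_n=k  ~  N( mu_k + A_k s_n , diag(psi_k)^-1 )
##   s_{n,l} | q_{n,l}=j  ~  N( eta_{k,l,j} , beta_{k,l}^-1 )
##   q_{n,l} ~ Cat(w_{k,l}),   c_n ~ Cat(pi)
## with conjugate priors: pi ~ Dir(alpha0), w ~ Dir(d0),
## mu ~ N(0, tau_mu^-1 I), A_{.,l} | alpha_l ~ N(0, alpha_l^-1) with
## ARD alpha_l ~ Gamma, noise psi_d ~ Gamma, source precisions
## beta_l ~ Gamma, component means eta ~ N(0, tau_eta^-1).
##
## Sources are location mixtures of Gaussians: the m components of source
## l share one precision beta_l and differ in their means.  This keeps
## every update conjugate and makes the source-posterior covariance
## identical across observations within a cluster, so a full sweep is a
## handful of dense matrix products rather than n small linear solves.
##
## The variational posterior factorises as
##   q = q(pi) prod_k [ q(mu_k) q(A_k) q(alpha_k) q(psi_k)
##                      prod_l q(beta_kl) q(w_kl) prod_j q(eta_klj) ]
##       prod_n [ q(c_n) prod_k q(s_n | c_n=k) prod_l q(q_nl | c_n=k) ]
## with q(A_k) factorised over rows (each row Gaussian with its own
## covariance, parameterised jointly through one eigendecomposition per
## cluster per sweep).  Every update below is the exact conditional
## optimum, so the evidence lower bound is non-decreasing sweep to sweep.

LOG2PI <- log(2 * pi)

## Symmetric fixed-point ICA rotation (tanh contrast) on whitened scores.
## Used only to orient the mixing-matrix initialisation toward the
## independent basis; rows of the returned matrix are orthonormal
## unmixing vectors.  Deterministic given seed_matrix.
fastica_rotation <- function(Tm, seed_matrix, max_iter = 100L, tol = 1e-6) {
  r <- ncol(Tm)
  n <- nrow(Tm)
  orth <- function(W) {
    s <- svd(W)
    s$u %*% t(s$v)
  }
  W <- orth(seed_matrix)
  for (it in seq_len(max_iter)) {
    U <- Tm %*% t(W)
    G <- tanh(U)
    Wn <- crossprod(G, Tm) / n - (colMeans(1 - G^2)) * W
    Wn <- orth(Wn)
    delta <- 1 - min(abs(diag(Wn %*% t(W))))
    W <- Wn
    if (delta < tol) break
  }
  W
}

cl_expectations <- function(cl) {
  list(
    psi_bar = gam_mean(cl$psi_a, cl$psi_b),
    Elogpsi = gam_logmean(cl$psi_a, cl$psi_b),
    alpha_bar = gam_mean(cl$alpha_a, cl$alpha_b),
    Elogalpha = gam_logmean(cl$alpha_a, cl$alpha_b),
    beta_bar = gam_mean(cl$beta_a, cl$beta_b),
    Elogbeta = gam_logmean(cl$beta_a, cl$beta_b),
    Elogw = digamma(cl$w_conc) - digamma(rowSums(cl$w_conc)),
    eta2 = cl$eta_mean^2 + cl$eta_var
  )
}

## sum_d wts_d * SigmaA_d, using the stored covariance parameterisation
## SigmaA_d = Ubig diag(1 / (psi_used_d * lam + 1)) Ubig'
sigmaA_weighted <- function(cl, wts) {
  aux <- cl$A_aux
  g <- colSums(wts / (outer(aux$psi_used, aux$lam) + 1))
  aux$Ubig %*% (g * t(aux$Ubig))
}

## E[ A' diag(psi) A ] under q(A), with the supplied noise means
eatpsia <- function(cl, psi_bar) {
  crossprod(cl$A_mean, psi_bar * cl$A_mean) + sigmaA_weighted(cl, psi_bar)
}

## Source-posterior update for one cluster: q(s_n | c_n=k) = N(M_n, Sigma)
e_step_cluster <- function(cl, Z, rho) {
  ex <- cl_expectations(cl)
  L <- ncol(cl$A_mean)
  n <- nrow(Z)
  m <- ncol(cl$eta_mean)
  Sprec <- eatpsia(cl, ex$psi_bar) + diag(ex$beta_bar, L)
  ch <- chol(Sprec)
  Sigma <- chol2inv(ch)
  logdet <- -2 * sum(log(diag(ch)))
  Etan <- matrix(0, n, L)
  for (l in seq_len(L))
    Etan[, l] <- rho[[l]] %*% cl$eta_mean[l, ]
  Zc <- sweep(Z, 2L, cl$mu_mean)
  M <- (Zc %*% (ex$psi_bar * cl$A_mean) +
          Etan * rep(ex$beta_bar, each = n)) %*% Sigma
  list(M = M, Sigma = Sigma, logdet = logdet)
}

## Source-component responsibilities q(q_nl = j | c_n = k)
rho_update <- function(cl, M, Sigma) {
  ex <- cl_expectations(cl)
  n <- nrow(M)
  L <- ncol(M)
  m <- ncol(cl$eta_mean)
  rho <- vector("list", L)
  for (l in seq_len(L)) {
    s2l <- M[, l]^2 + Sigma[l, l]
    quad <- s2l - 2 * tcrossprod(M[, l], cl$eta_mean[l, ]) +
      rep(ex$eta2[l, ], each = n)
    logw <- rep(ex$Elogw[l, ] + 0.5 * ex$Elogbeta[l], each = n) -
      0.5 * ex$beta_bar[l] * quad
    rho[[l]] <- softmax_rows(matrix(logw, n, m))
  }
  rho
}

## Full conditional update of the cluster's global factors, in the fixed
## order: A, alpha, mu, psi, (w, eta, beta).  rk are the cluster
## responsibilities, (M, Sigma, rho) the current per-observation factors.
m_step_cluster <- function(cl, Z, rk, M, Sigma, rho, priors) {
  n <- nrow(Z); D <- ncol(Z)
  L <- ncol(cl$A_mean); m <- ncol(cl$eta_mean)
  ex <- cl_expectations(cl)
  Nk <- sum(rk)
  S <- Nk * Sigma + crossprod(M, rk * M)

  ## --- mixing matrix rows: q(a_d) = N(A_mean[d,], SigmaA_d) with
  ##     SigmaA_d = (psi_d S + diag(alpha))^-1, via one eigendecomposition
  Zc <- sweep(Z, 2L, cl$mu_mean)
  Bmat <- crossprod(Zc * rk, M)
  W <- 1 / sqrt(ex$alpha_bar)
  St <- S * outer(W, W)
  eg <- eigen(St, symmetric = TRUE)
  lam <- pmax(eg$values, 0)
  Ubig <- W * eg$vectors
  f <- 1 / (outer(ex$psi_bar, lam) + 1)           # D x L
  C <- Bmat %*% Ubig
  cl$A_mean <- ((ex$psi_bar * C) * f) %*% t(Ubig)
  cl$VarA <- f %*% t(Ubig^2)
  cl$A_aux <- list(
    Ubig = Ubig, lam = lam, psi_used = ex$psi_bar,
    entropy = 0.5 * D * L * (LOG2PI + 1) +
      0.5 * (-D * sum(log(ex$alpha_bar)) + sum(log(f)))
  )

  ## --- ARD precisions on the columns of A
  cl$alpha_a <- rep(priors$a_alpha + D / 2, L)
  cl$alpha_b <- priors$b_alpha + 0.5 * colSums(cl$A_mean^2 + cl$VarA)

  ## --- cluster mean
  P <- M %*% t(cl$A_mean)
  prec_mu <- priors$tau_mu + Nk * ex$psi_bar
  cl$mu_mean <- ex$psi_bar * colSums(rk * (Z - P)) / prec_mu
  cl$mu_var <- 1 / prec_mu

  ## --- diagonal noise precisions (expected squared residuals use the
  ##     just-updated A and mu; tr(SigmaA_d S) = sum_i lam_i f_di because
  ##     Ubig diagonalises S by construction)
  Zc <- sweep(Z, 2L, cl$mu_mean)
  Resid <- Zc - P
  term_aSa <- rowSums((cl$A_mean %*% S) * cl$A_mean)
  term_tr <- as.vector(f %*% lam)
  ss <- colSums(rk * Resid^2) + Nk * cl$mu_var + term_aSa + term_tr -
    colSums(rk * P^2)
  cl$psi_a <- rep(priors$a_psi + Nk / 2, D)
  cl$psi_b <- priors$b_psi + 0.5 * pmax(ss, .Machine$double.eps)

  ## --- source mixtures: component weights, means, then precisions
  s2 <- M^2 + rep(diag(Sigma), each = n)
  for (l in seq_len(L)) {
    Rw <- rk * rho[[l]]
    counts <- colSums(Rw)
    cl$w_conc[l, ] <- priors$d0 + counts
    rm_l <- colSums(Rw * M[, l])
    eta_prec <- priors$tau_eta + ex$beta_bar[l] * counts
    cl$eta_mean[l, ] <- ex$beta_bar[l] * rm_l / eta_prec
    cl$eta_var[l, ] <- 1 / eta_prec
    qsum <- sum(rk * s2[, l]) - 2 * sum(cl$eta_mean[l, ] * rm_l) +
      sum(counts * (cl$eta_mean[l, ]^2 + cl$eta_var[l, ]))
    cl$beta_a[l] <- priors$a_beta + Nk / 2
    cl$beta_b[l] <- priors$b_beta + 0.5 * max(qsum, .Machine$double.eps)
  }
  cl
}

## Per-observation, per-cluster variational free energy F[n, k]:
## E[log p(y_n, s_n, q_n | c_n=k)] - E[log q(s_n, q_n | c_n=k)] under the
## current factors.  Cluster responsibilities are softmax(Elog pi + F).
compute_F <- function(model, Z, cache) {
  n <- nrow(Z); D <- ncol(Z)
  Fm <- matrix(0, n, model$K)
  for (k in seq_len(model$K)) {
    cl <- model$clusters[[k]]
    es <- cache$cl[[k]]
    ex <- cl_expectations(cl)
    L <- ncol(cl$A_mean); m <- ncol(cl$eta_mean)
    G <- eatpsia(cl, ex$psi_bar)
    Zc <- sweep(Z, 2L, cl$mu_mean)
    P <- es$M %*% t(cl$A_mean)
    Resid <- Zc - P
    S1 <- drop(Resid^2 %*% ex$psi_bar)
    P2 <- drop(P^2 %*% ex$psi_bar)
    mGm <- rowSums((es$M %*% G) * es$M)
    F1 <- 0.5 * sum(ex$Elogpsi) - 0.5 * D * LOG2PI -
      0.5 * (S1 + sum(ex$psi_bar * cl$mu_var) + sum(G * es$Sigma) + mGm - P2)
    F23 <- numeric(n)
    for (l in seq_len(L)) {
      rho_l <- es$rho[[l]]
      s2l <- es$M[, l]^2 + es$Sigma[l, l]
      quad <- s2l - 2 * tcrossprod(es$M[, l], cl$eta_mean[l, ]) +
        rep(ex$eta2[l, ], each = n)
      F23 <- F23 + 0.5 * ex$Elogbeta[l] - 0.5 * LOG2PI -
        0.5 * ex$beta_bar[l] * rowSums(rho_l * quad) +
        drop(rho_l %*% ex$Elogw[l, ]) -
        rowSums(rho_l * log(pmax(rho_l, 1e-300)))
    }
    F4 <- 0.5 * (L * (LOG2PI + 1) + es$logdet)
    Fm[, k] <- F1 + F23 + F4
  }
  Fm
}

## Evidence lower bound at the current variational parameters.
elbo_value <- function(model, Z, cache) {
  priors <- model$priors
  Elogpi <- dir_logmean(model$pi_conc)
  data_part <- sum(cache$r * sweep(cache$F, 2L, Elogpi, "+")) -
    xlogx_sum(cache$r)
  kl <- kl_dirichlet(model$pi_conc, rep(priors$alpha0, model$K))
  for (cl in model$clusters) {
    ex <- cl_expectations(cl)
    D <- length(cl$mu_mean); L <- ncol(cl$A_mean)
    kl <- kl + kl_normal0(cl$mu_mean, cl$mu_var, priors$tau_mu)
    Elogp_A <- 0.5 * D * sum(ex$Elogalpha) - 0.5 * D * L * LOG2PI -
      0.5 * sum(ex$alpha_bar * colSums(cl$A_mean^2 + cl$VarA))
    kl <- kl - (Elogp_A + cl$A_aux$entropy)
    kl <- kl + kl_gamma(cl$alpha_a, cl$alpha_b, priors$a_alpha, priors$b_alpha)
    kl <- kl + kl_gamma(cl$psi_a, cl$psi_b, priors$a_psi, priors$b_psi)
    kl <- kl + kl_gamma(cl$beta_a, cl$beta_b, priors$a_beta, priors$b_beta)
    for (l in seq_len(L))
      kl <- kl + kl_dirichlet(cl$w_conc[l, ], rep(priors$d0, ncol(cl$w_conc)))
    kl <- kl + kl_normal0(cl$eta_mean, cl$eta_var, priors$tau_eta)
  }
  data_part - kl
}

## (Re)build the per-observation cache: uniform component
## responsibilities, one source-posterior pass, free energies, and
## cluster responsibilities.  Used at initialisation and after reload.
build_cache <- function(model, Z) {
  n <- nrow(Z)
  cache <- list(cl = vector("list", model$K))
  for (k in seq_len(model$K)) {
    cl <- model$clusters[[k]]
    L <- ncol(cl$A_mean); m <- ncol(cl$eta_mean)
    rho <- rep(list(matrix(1 / m, n, m)), L)
    es <- e_step_cluster(cl, Z, rho)
    es$rho <- rho_update(cl, es$M, es$Sigma)
    cache$cl[[k]] <- es
  }
  cache$F <- compute_F(model, Z, cache)
  cache$r <- softmax_rows(sweep(cache$F, 2L, dir_logmean(model$pi_conc), "+"))
  cache
}

ensure_cache <- function(model, Z) {
  cache <- model$cache
  if (is.null(cache) || nrow(cache$r) != nrow(Z)) cache <- build_cache(model, Z)
  cache
}
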