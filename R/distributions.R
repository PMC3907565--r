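## Conjugate-exponential-family helpers shared by the variational engine.
## All Gammas are shape/rate; all "logmean" quantities are E[log x] under
## the named posterior.

gam_mean <- function(a, b) a / b
gam_logmean <- function(a, b) digamma(a) - log(b)

## KL( Gamma(a,b) || Gamma(a0,b0) ), elementwise-summed
kl_gamma <- function(a, b, a0, b0) {
  sum((a - a0) * digamma(a) - lgamma(a) + lgamma(a0) +
        a0 * (log(b) - log(b0)) + a * (b0 - b) / b)
}

dir_logmean <- function(conc) digamma(conc) - digamma(sum(conc))

## KL( Dir(conc) || Dir(conc0) )
kl_dirichlet <- function(conc, conc0) {
  s <- sum(conc)
  sum(lgamma(conc0)) - lgamma(sum(conc0)) - sum(lgamma(conc)) + lgamma(s) +
    sum((conc - conc0) * (digamma(conc) - digamma(s)))
}

## KL( N(m, v) || N(0, 1/tau) ), elementwise-summed
kl_normal0 <- function(m, v, tau) {
  sum(0.5 * (tau * (m^2 + v) - 1 - log(tau) - log(v)))
}

## row-wise softmax of a matrix of log-weights; returns probabilities
softmax_rows <- function(logw) {
  mx <- logw[, 1L]
  for (j in seq_len(ncol(logw))[-1L]) mx <- pmax(mx, logw[, j])
  w <- exp(logw - mx)
  w / rowSums(w)
}

## sum of p*log(p) with 0 log 0 = 0
xlogx_sum <- function(p) {
  pos <- p > 0
  sum(p[pos] * log(p[pos]))
}
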