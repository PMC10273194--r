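# Shared fixture builders: everything is generated in code at test time.

# Small random censored dataset with controllable censoring fraction.
make_toy_surv <- function(n = 30, p = 4, seed = 1, censor = 0.3,
                          hazard_beta = NULL) {
  with_seed <- survsel:::with_seed
  with_seed(seed, {
    X <- matrix(stats::rnorm(n * p), n, p,
                dimnames = list(NULL, paste0("f", seq_len(p))))
    eta <- if (is.null(hazard_beta)) rep(0, n) else as.numeric(X %*% hazard_beta)
    T_lat <- stats::rexp(n, rate = exp(eta))
    C_lat <- stats::quantile(T_lat, probs = 1 - censor) *
      stats::runif(n, 0.5, 2)
    list(X = X, time = pmin(T_lat, C_lat),
         status = as.integer(T_lat <= C_lat), eta = eta)
  })
}

# Signal-free survival data: features carry no information about the outcome.
make_null_surv <- function(n = 200, p = 50, seed = 1) {
  survsel:::with_seed(seed, {
    X <- matrix(stats::rnorm(n * p), n, p)
    T_lat <- stats::rexp(n, 1)
    C_lat <- stats::rexp(n, 1 / 5)
    list(X = X, time = pmin(T_lat, C_lat), status = as.integer(T_lat <= C_lat))
  })
}

# Brute-force concordance over all pairs, written independently of the
# vectorized implementation.
cindex_bruteforce <- function(scores, time, status, tie_credit = 0.5) {
  num <- den <- 0
  n <- length(time)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (status[i] == 1 && time[i] < time[j]) {
      den <- den + 1
      if (scores[i] > scores[j]) num <- num + 1
      else if (scores[i] == scores[j]) num <- num + tie_credit
    }
  }
  num / den
}

# Direct-summation Brier score oracle following the defining formula term by
# term, with its own step-function evaluation.
brier_bruteforce <- function(t, pred, time, status, km_time, km_surv) {
  stepfun_right <- function(tt) {
    if (tt < km_time[1]) return(1)
    km_surv[max(which(km_time <= tt))]
  }
  stepfun_left <- function(tt) {
    if (all(km_time >= tt)) return(1)
    km_surv[max(which(km_time < tt))]
  }
  n <- length(time)
  acc <- 0
  for (i in seq_len(n)) {
    if (time[i] < t && status[i] == 1) {
      acc <- acc + pred[i]^2 / stepfun_left(time[i])
    } else if (time[i] > t) {
      acc <- acc + (1 - pred[i])^2 / stepfun_right(t)
    }
  }
  acc / n
}
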