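# Shared fixtures and independent oracles used across the suite.

# small synthetic cohort: quick to generate, still exercises pairing,
# blocks and both tasks
small_spec <- function(seed = 5L, ...) {
  args <- modifyList(
    list(n_subjects = 20L, n_day1_only = 8L, n_features = 40L,
         n_informative_time = 5L, n_informative_neuropathy = 3L,
         n_blocks = 4L, missing_rate = 0, n_decoys = 5L, seed = seed),
    list(...))
  do.call(synthetic_spec, args)
}

# a standardized dataset straight from a matrix (rows get synthetic ids)
matrix_dataset <- function(x, standardized = TRUE) {
  n <- nrow(x)
  if (is.null(rownames(x))) rownames(x) <- sprintf("s%03d", seq_len(n))
  if (is.null(colnames(x))) colnames(x) <- sprintf("f%03d", seq_len(ncol(x)))
  samples <- tibble::tibble(sample_id = rownames(x),
                            subject_id = rownames(x),
                            timepoint = "day1", neuropathy = "unknown")
  ds <- lipid_dataset(x, samples)
  ds$standardized <- standardized
  ds$log_transformed <- TRUE
  ds
}

# --- independent cABC oracle: plain loops over all candidate curve points
oracle_cabc <- function(values) {
  n <- length(values)
  ord <- order(-values, seq_along(values))
  v <- values[ord]
  y <- cumsum(v) / sum(v)
  x <- seq_len(n) / n
  best <- 1L; best_d <- Inf
  for (i in seq_len(n)) {
    d <- sqrt(x[i]^2 + (y[i] - 1)^2)
    if (d < best_d) { best_d <- d; best <- i }
  }
  bc <- n
  xprev <- 0; yprev <- 0
  for (i in seq_len(n)) {
    slope <- (y[i] - yprev) / (x[i] - xprev)
    if (slope < 1) { bc <- i - 1L; break }
    xprev <- x[i]; yprev <- y[i]
  }
  if (bc < best) bc <- best
  list(ab_index = best, bc_index = bc)
}

# --- Fisher 2x2 oracles by hypergeometric enumeration / CI inversion
oracle_fisher_p <- function(tab) {
  x <- tab[1, 1]
  m1 <- sum(tab[1, ]); m2 <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - m2):min(k, m1)
  probs <- dhyper(support, m1, m2, k)
  obs <- dhyper(x, m1, m2, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# noncentral hypergeometric pmf over the support, given odds ratio psi
nchg_pmf <- function(psi, m1, m2, k) {
  support <- max(0, k - m2):min(k, m1)
  logw <- lchoose(m1, support) + lchoose(m2, k - support) +
    support * log(psi)
  w <- exp(logw - max(logw))
  list(support = support, p = w / sum(w))
}

oracle_fisher_or <- function(tab) {
  x <- tab[1, 1]
  m1 <- sum(tab[1, ]); m2 <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - m2):min(k, m1)
  if (x == min(support)) return(0)
  if (x == max(support)) return(Inf)
  # conditional MLE: E_psi[X] == x
  f <- function(logpsi) {
    d <- nchg_pmf(exp(logpsi), m1, m2, k)
    sum(d$support * d$p) - x
  }
  exp(uniroot(f, c(-25, 25), tol = 1e-10)$root)
}

oracle_fisher_ci <- function(tab, level = 0.95) {
  x <- tab[1, 1]
  m1 <- sum(tab[1, ]); m2 <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - m2):min(k, m1)
  a <- (1 - level) / 2
  p_ge <- function(psi) { d <- nchg_pmf(psi, m1, m2, k); sum(d$p[d$support >= x]) }
  p_le <- function(psi) { d <- nchg_pmf(psi, m1, m2, k); sum(d$p[d$support <= x]) }
  lo <- if (x == min(support)) 0 else
    exp(uniroot(function(lp) p_ge(exp(lp)) - a, c(-40, 40), tol = 1e-10)$root)
  hi <- if (x == max(support)) Inf else
    exp(uniroot(function(lp) p_le(exp(lp)) - a, c(-40, 40), tol = 1e-10)$root)
  c(lo, hi)
}

# --- Kruskal-Wallis oracle from the defining rank formula (midranks, tie
# correction applied explicitly)
oracle_kruskal_h <- function(groups) {
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), lengths(groups))
  n <- length(x)
  r <- rank(x) # midranks
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, g, function(ri) length(ri) * (mean(ri) - (n + 1) / 2)^2))
  ties <- table(x)
  correction <- 1 - sum(ties^3 - ties) / (n^3 - n)
  h / correction
}

# --- Benjamini-Hochberg step-up by hand
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}

# standardize holdout with training statistics (mirrors the pipeline step)
scale_with_train <- function(holdout, train_std) {
  mu <- attr(train_std, "standardization_means")[colnames(holdout$values)]
  sds <- attr(train_std, "standardization_sds")[colnames(holdout$values)]
  holdout$values <- sweep(sweep(holdout$values, 2L, mu, `-`), 2L, sds, `/`)
  holdout$standardized <- TRUE
  holdout
}
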