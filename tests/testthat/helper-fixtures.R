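# Fixture builders used across the suite. Everything is generated in code;
# no binary fixtures.

# Peak table from a subjects x vocs matrix of single-fragment areas.
# TIC defaults to 3x the fragment area.
pt_from_matrix <- function(areas, groups, tic = NULL, mz = 50L,
                           voc_ids = colnames(areas)) {
  if (is.null(voc_ids)) voc_ids <- sprintf("v%02d", seq_len(ncol(areas)))
  subj <- sprintf("s%02d", seq_len(nrow(areas)))
  if (is.null(tic)) tic <- 3 * areas
  species <- tibble::tibble(
    voc_id = voc_ids, name = voc_ids, cas = "", chemical_class = "test",
    retention_time_min = seq_len(ncol(areas)) + 5,
    fragment_mzs = rep(list(as.integer(mz)), ncol(areas)),
    quantifier_mz = NA_integer_, confirmed_standard = TRUE
  )
  subjects <- tibble::tibble(subject_id = subj, group = groups)
  frag <- tibble::tibble(
    subject_id = rep(subj, times = ncol(areas)),
    voc_id = rep(voc_ids, each = nrow(areas)),
    mz = as.integer(mz), area = as.vector(areas)
  )
  tict <- tibble::tibble(
    subject_id = rep(subj, times = ncol(areas)),
    voc_id = rep(voc_ids, each = nrow(areas)),
    tic_area = as.vector(tic)
  )
  as_peak_table(species, subjects, frag, tict)
}

groups_9v9 <- c(rep("positive", 9), rep("control", 9))

# Brute-force Mann-Whitney: exact two-tailed p by enumerating every group
# assignment of the pooled sample (tie-free data). Independent of the DP
# implementation under test.
brute_force_mw_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  u_of <- function(idx) {
    xs <- pooled[idx]; ys <- pooled[-idx]
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  u_obs <- u_of(seq_len(n1))
  us <- combn(n1 + n2, n1, u_of)
  p_ge <- mean(us >= u_obs)
  p_le <- mean(us <= u_obs)
  list(u = u_obs, p_one = min(p_ge, p_le),
       p_two = min(1, 2 * min(p_ge, p_le)))
}

# Direct Gaussian log-density-difference oracle for the QDA score.
log_density_diff <- function(x, mu_pos, sigma_pos, mu_ctrl, sigma_ctrl,
                             prior_ratio = 1) {
  ld <- function(v, mu, S) {
    p <- length(mu)
    -0.5 * (p * log(2 * pi) +
            as.numeric(determinant(S, logarithm = TRUE)$modulus) +
            drop(t(v - mu) %*% solve(S) %*% (v - mu)))
  }
  ld(x, mu_pos, sigma_pos) - ld(x, mu_ctrl, sigma_ctrl) + log(prior_ratio)
}

# Random positive-definite matrix.
rand_pd <- function(p) {
  a <- matrix(rnorm(p * p), p)
  crossprod(a) + diag(p) * 0.5
}
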