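# Independent brute-force oracles and small fixture builders used across the
# suite. These deliberately avoid the package's optimized code paths.

# literal double sum of the screened Coulomb kernel over all cross pairs
naive_pair_energy <- function(a, b, params) {
  lb <- params$bjerrum_nm
  kappa <- if (is.finite(params$screening_length_nm))
    1 / params$screening_length_nm else 0
  cutoff <- params$cutoff_nm
  e <- 0
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      r <- sqrt((a$x_nm[i] - b$x_nm[j])^2 + (a$z_nm[i] - b$z_nm[j])^2)
      if (r > cutoff) next
      e <- e + a$charge[i] * b$charge[j] * lb * exp(-kappa * r) / r
    }
  }
  e
}

# vectorized literal sum (outer products); independent of the C++ kernel
outer_pair_energy <- function(a, b, params) {
  lb <- params$bjerrum_nm
  kappa <- if (is.finite(params$screening_length_nm))
    1 / params$screening_length_nm else 0
  r <- sqrt(outer(a$x_nm, b$x_nm, "-")^2 + outer(a$z_nm, b$z_nm, "-")^2)
  k <- lb * exp(-kappa * r) / r
  k[r > params$cutoff_nm] <- 0
  as.numeric(a$charge %*% k %*% b$charge)
}

as_chain <- function(q, label = "chain") {
  n <- length(q)
  structure(
    tibble::tibble(site = 0:(n - 1),
                   position_nm = (0:(n - 1)) * rod_spacing_nm,
                   charge = as.numeric(q)),
    label = label, spacing = rod_spacing_nm,
    class = c("charge_chain", class(tibble::tibble())))
}

random_chain <- function(n, seed, label = paste0("rand", seed)) {
  set.seed(seed)
  as_chain(sample(c(-2, 0, 0, 2), n, replace = TRUE), label)
}

toy_rod <- function(n = 280, ...)
  synthetic_rod(n_sites = n, repeat_sites = 98, tip_sites = 20, ...)

expect_tibble <- function(x, cols) {
  expect_s3_class(x, "tbl_df")
  expect_true(all(cols %in% names(x)))
}
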