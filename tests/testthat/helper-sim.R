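# Small shared builders for the test suite.

# compact simulation: few genes, quick DE runs
small_config <- function(...) {
  defaults <- list(n_genes = 400, targets_per_mirna = 10,
                   n_fp_signature = 20)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# hand-built 3-gene x 4-sample microarray series
toy_series <- function(kind = "microarray") {
  values <- matrix(
    c(5.2, 4.8, 3.1, 2.9,
      2.0, 3.0, 2.0, 3.0,
      1.0, 3.0, 2.0, 4.0),
    nrow = 3, byrow = TRUE,
    dimnames = list(c("gA", "gB", "gC"),
                    c("s1", "s2", "s3", "s4"))
  )
  expression_series("toy", kind, values,
                    c(s1 = "RA", s2 = "RA", s3 = "HC", s4 = "HC"))
}

# independent second-route Welch evaluation (never calls t.test)
welch_by_formula <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- sum((x - mean(x))^2) / (nx - 1)
  vy <- sum((y - mean(y))^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# independent step-up BH (never calls p.adjust)
bh_by_formula <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- p[o] * n / seq_len(n)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(n)
  q[o] <- pmin(q_sorted, 1)
  q
}

# upper-tail hypergeometric by explicit combinatorial sum (never phyper)
hyper_upper_by_sum <- function(k, m_a, m_b, N) {
  j <- seq(k, min(m_a, m_b))
  sum(choose(m_a, j) * choose(N - m_a, m_b - j)) / choose(N, m_b)
}
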