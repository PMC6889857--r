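# Independent oracles and fixture builders shared across the suite.
# Everything here recomputes quantities from first principles (closed
# forms, brute-force enumeration, naive summation, grid quadrature) and
# must stay independent of the package implementation it checks.

# concentration at which a Hill fit produces a given %block
conc_for_block <- function(ic50, hill, block) {
  ic50 * (block / (100 - block))^(1 / hill)
}

# naive re-implementation of the static net-block sum
naive_static_bnet <- function(drug, multiple, channels = bnet_channels(),
                              ignore_hill = FALSE) {
  conc <- multiple * drug$cmax_free
  total <- 0
  for (ch in intersect(channels, names(drug$fits))) {
    f <- drug$fits[[ch]]
    h <- if (ignore_hill || is.na(f$hill)) 1 else f$hill
    b <- 100 * conc^h / (conc^h + f$ic50^h)
    total <- total + if (ch == "IKr") b else -b
  }
  total
}

# naive re-implementation of the dynamic variant (1x Cmax)
naive_dynamic_bnet <- function(drug) {
  conc <- drug$cmax_free
  dyn <- drug$dynamic_herg
  h <- if (is.na(dyn$dyn_hill)) 1 else dyn$dyn_hill
  total <- 100 * dyn$max_inhibition * conc^h / (conc^h + dyn$dyn_ic50^h)
  for (ch in intersect(c("INaL", "ICaL", "INa"), names(drug$fits))) {
    f <- drug$fits[[ch]]
    h <- if (is.na(f$hill)) 1 else f$hill
    total <- total - 100 * conc^h / (conc^h + f$ic50^h)
  }
  total
}

# brute-force all-pairs Mann-Whitney AUC with half-credit for ties
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# direct binomial log-likelihood of a univariable logistic model
direct_loglik <- function(intercept, slope, scores, y) {
  p <- stats::plogis(intercept + slope * scores)
  sum(y * log(p) + (1 - y) * log(1 - p))
}

# random valid drug with all optional structure exercised
random_drug <- function(name, p_missing_depol = 0.3, p_dynamic = 0.7) {
  cmax <- 10^stats::runif(1, -3, 1)
  fits <- list(IKr = hill_fit(10^stats::runif(1, -3, 3),
                              if (stats::runif(1) < 0.2) NA else
                                stats::runif(1, 0.5, 2),
                              stats::runif(1) < 0.2))
  for (ch in c("INaL", "ICaL", "INa")) {
    if (stats::runif(1) >= p_missing_depol)
      fits[[ch]] <- hill_fit(10^stats::runif(1, -2, 3),
                             stats::runif(1, 0.5, 2))
  }
  dyn <- NULL
  if (stats::runif(1) < p_dynamic)
    dyn <- dynamic_herg_fit(fits$IKr$ic50 * 10^stats::runif(1, 0, 1),
                            stats::runif(1),
                            if (stats::runif(1) < 0.5) NA else
                              stats::runif(1, 0.5, 2))
  drug_record(name, cmax_free = cmax, fits = fits,
              risk = sample(c(NA, "low", "intermediate", "high"), 1),
              dataset = sample(c(NA, "training", "validation"), 1),
              dynamic_herg = dyn,
              external_metric = if (stats::runif(1) < 0.5) NA_real_ else
                stats::rnorm(1))
}

random_panel <- function(n = 10) {
  drug_panel(lapply(seq_len(n), function(i)
    random_drug(sprintf("drug_%03d", i))))
}

# field-level panel equality, ignoring free-text metadata
expect_panel_equal <- function(a, b) {
  expect_equal(length(a$drugs), length(b$drugs))
  for (i in seq_along(a$drugs)) {
    da <- a$drugs[[i]]; db <- b$drugs[[i]]
    expect_identical(da$name, db$name)
    expect_identical(da$cmax_free, db$cmax_free)
    expect_identical(da$risk, db$risk)
    expect_identical(da$dataset, db$dataset)
    expect_identical(da$external_metric, db$external_metric)
    expect_identical(names(da$fits), names(db$fits))
    for (ch in names(da$fits)) expect_identical(da$fits[[ch]], db$fits[[ch]])
    expect_identical(da$dynamic_herg, db$dynamic_herg)
  }
  invisible(NULL)
}

# ---- grid-quadrature oracle for the synthetic generative world ----
#
# %block at m x Cmax depends on a fit only through the log10 potency
# margin z = log10(ic50 / cmax) and the Hill coefficient h:
#   block = 100 / (1 + (10^z / m)^h).
# The oracle discretises the block distribution of each channel on a
# fixed grid by quadrature over (z, h), convolves the depolarizing
# channels (with the missing-fit point mass at zero), convolves against
# the repolarizing term, and integrates P(B_pos > B_neg) between
# categories. It never calls the generator or the scoring code.

.oracle_nbin <- 2001L  # block grid 0..100, width 0.05

oracle_block_pmf <- function(mu, sd, hill_range, multiple,
                             nbin = .oracle_nbin, nz = 241L, nh = 41L) {
  width <- 100 / (nbin - 1)
  if (sd > 0) {
    zq <- seq(mu - 6 * sd, mu + 6 * sd, length.out = nz)
    wz <- stats::dnorm(zq, mu, sd)
    wz <- wz / sum(wz)
  } else {
    zq <- mu; wz <- 1
  }
  if (diff(hill_range) > 0) {
    hq <- seq(hill_range[1], hill_range[2], length.out = nh)
  } else hq <- hill_range[1]
  wh <- rep(1 / length(hq), length(hq))
  blocks <- 100 / (1 + outer(10^zq / multiple, hq, `^`))
  w <- outer(wz, wh)
  k <- round(blocks / width) + 1L
  p <- numeric(nbin)
  for (i in seq_along(k)) p[k[i]] <- p[k[i]] + w[i]
  p
}

oracle_conv <- function(a, b) {
  # full linear convolution of two pmfs on a shared uniform grid
  stats::convolve(a, rev(b), type = "open")
}

# pmf of the net-block score for one risk category, on the grid
# value(k) = (k - nD) * width where nD = length of the summed
# depolarizing pmf
oracle_bnet_pmf <- function(config, category) {
  hm <- config$herg_margin_log10[[category]]
  dm <- config$depol_margin_log10[[category]]
  p_r <- oracle_block_pmf(hm[1], hm[2], config$hill_range, 5)
  p_d1 <- oracle_block_pmf(dm[1], dm[2], config$hill_range, 5)
  miss <- config$missing_depol_prob
  p_d1 <- (1 - miss) * p_d1
  p_d1[1] <- p_d1[1] + miss
  p_d <- oracle_conv(oracle_conv(p_d1, p_d1), p_d1)
  p_d <- pmax(p_d, 0)  # FFT round-off
  p_d <- p_d / sum(p_d)
  p_b <- pmax(oracle_conv(p_r, rev(p_d)), 0)
  p_b / sum(p_b)
}

# P(B_a > B_b) + 0.5 P(grid tie) for two categories
oracle_exceed_prob <- function(p_a, p_b) {
  cdf_b <- cumsum(p_b)
  sum(p_a * (c(0, cdf_b[-length(cdf_b)]) + 0.5 * p_b))
}

# expected low-vs-rest AUC under the generative world: the Mann-Whitney
# estimator is unbiased for the pairwise exceedance probability, so the
# expectation is the count-weighted mixture over positive categories
oracle_auc_low_vs_rest <- function(config) {
  p_low <- oracle_bnet_pmf(config, "low")
  p_int <- oracle_bnet_pmf(config, "intermediate")
  p_high <- oracle_bnet_pmf(config, "high")
  n_int <- config$n_per_category[["intermediate"]]
  n_high <- config$n_per_category[["high"]]
  (n_int * oracle_exceed_prob(p_int, p_low) +
     n_high * oracle_exceed_prob(p_high, p_low)) / (n_int + n_high)
}

# frozen checksum of the canonical serialisation of the packaged hERG
# validation table (name|ic50|hill|censoring per drug, table order)
FIXTURE_MD5 <- "307a628fac3f6698e98c22035f9be9d9"
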