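test_that("net block is the signed sum of channel blocks", {
  # force blocks {IKr: 80, INaL: 10, ICaL: 20, INa: 5} at 5 x Cmax = 1
  cmax <- 0.2
  conc <- 5 * cmax
  hills <- c(IKr = 1.2, INaL = 0.8, ICaL = 1.5, INa = 1)
  want <- c(IKr = 80, INaL = 10, ICaL = 20, INa = 5)
  fits <- lapply(names(want), function(ch) {
    # invert the Hill curve: pick the IC50 giving the wanted block at conc
    hill_fit(conc / ((want[[ch]] / (100 - want[[ch]]))^(1 / hills[[ch]])),
             hills[[ch]])
  })
  names(fits) <- names(want)
  d <- drug_record("forced", cmax_free = cmax, fits = fits)
  r <- bnet(d, 5)
  expect_equal(r$bnet, 45, tolerance = 1e-9)
  expect_equal(r$channel_blocks[names(want)], want, tolerance = 1e-9,
               ignore_attr = FALSE)
  expect_length(r$missing_channels, 0)
  # the stored decomposition re-sums to the score
  signs <- ifelse(names(r$channel_blocks) == "IKr", 1, -1)
  expect_equal(sum(signs * r$channel_blocks), r$bnet, tolerance = 1e-9)
})

test_that("missing channels contribute zero but stay visible", {
  d <- drug_record("herg_only", cmax_free = 2,
                   fits = list(IKr = hill_fit(10, 1)))
  r <- bnet(d, 5)  # C = 10 = IC50
  expect_equal(r$bnet, 50)
  expect_setequal(r$missing_channels, c("INaL", "ICaL", "INa"))
})

test_that("no block anywhere gives a near-zero score", {
  fits <- lapply(bnet_channels(), function(ch) hill_fit(1e12, 1))
  names(fits) <- bnet_channels()
  d <- drug_record("inert", cmax_free = 1, fits = fits)
  expect_equal(bnet(d, 5)$bnet, 0, tolerance = 1e-6)
})

test_that("incomplete records are rejected with a reason", {
  expect_error(bnet(drug_record("nocmax",
                                fits = list(IKr = hill_fit(1, 1)))),
               "cmax_free")
  expect_error(bnet(drug_record("noherg", cmax_free = 1,
                                fits = list(INa = hill_fit(1, 1)))),
               "IKr")
  expect_error(bnet(drug_record("x", cmax_free = 1,
                                fits = list(IKr = hill_fit(1, 1))),
                    multiple = 0), "multiple")
  expect_error(dynamic_bnet(drug_record("nodyn", cmax_free = 1)),
               "dynamic")
})

test_that("score moves the right way when potencies move", {
  set.seed(21)
  base <- drug_record("m", cmax_free = 1,
                      fits = list(IKr = hill_fit(3, 1.1),
                                  ICaL = hill_fit(8, 0.9)))
  # strictly decreasing in the IKr ic50
  v <- vapply(c(0.5, 1, 5, 20), function(x) {
    d <- base; d$fits$IKr <- hill_fit(x, 1.1); bnet(d, 5)$bnet
  }, numeric(1))
  expect_true(all(diff(v) < 0))
  # strictly increasing in a depolarizing ic50
  v <- vapply(c(0.5, 1, 5, 20), function(x) {
    d <- base; d$fits$ICaL <- hill_fit(x, 0.9); bnet(d, 5)$bnet
  }, numeric(1))
  expect_true(all(diff(v) > 0))
  # hERG-only score is strictly increasing in the Cmax multiple
  herg <- drug_record("h", cmax_free = 1, fits = list(IKr = hill_fit(4, 1.3)))
  v <- vapply(c(1, 2, 5, 10), function(m) bnet(herg, m)$bnet, numeric(1))
  expect_true(all(diff(v) > 0))
})

test_that("library score equals the naive summation oracle", {
  set.seed(22)
  for (i in 1:100) {
    d <- random_drug(sprintf("d%03d", i))
    m <- sample(c(1, 5, 10), 1)
    expect_equal(bnet(d, m)$bnet, naive_static_bnet(d, m),
                 tolerance = 1e-12)
    if (!is.null(d$dynamic_herg))
      expect_equal(dynamic_bnet(d)$bnet, naive_dynamic_bnet(d),
                   tolerance = 1e-12)
  }
})

test_that("the original-form settings reproduce a unit-Hill 1x score", {
  # Hill forced to 1 everywhere, INa excluded, evaluated at 1x Cmax
  set.seed(23)
  for (i in 1:50) {
    d <- random_drug(sprintf("d%03d", i))
    got <- bnet(d, multiple = 1, channels = c("IKr", "INaL", "ICaL"),
                ignore_hill = TRUE)$bnet
    want <- naive_static_bnet(d, 1, channels = c("IKr", "INaL", "ICaL"),
                              ignore_hill = TRUE)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("scores respect the [-300, 100] bounds", {
  set.seed(24)
  for (i in 1:50) {
    d <- random_drug(sprintf("d%03d", i))
    b <- bnet(d, 10)$bnet
    expect_gte(b, -300); expect_lte(b, 100)
  }
})

test_that("dynamic variant combines dynamic hERG with static depolarizers", {
  d <- drug_record("z", cmax_free = 1,
                   dynamic_herg = dynamic_herg_fit(1, 0))
  expect_identical(dynamic_bnet(d)$bnet, 0)

  d <- drug_record("z", cmax_free = 2,
                   dynamic_herg = dynamic_herg_fit(2, 1, 1))
  r <- dynamic_bnet(d)
  expect_equal(r$bnet, 50)
  expect_identical(r$variant, "dynamic")
  expect_identical(r$multiple, 1)

  # dyn hERG 60% with static {ICaL: 25, INa: 5} -> 30
  cmax <- 1
  d <- drug_record("z", cmax_free = cmax,
                   fits = list(
                     ICaL = hill_fit(cmax / ((25 / 75)^(1 / 1)), 1),
                     INa = hill_fit(cmax / ((5 / 95)^(1 / 1)), 1)),
                   dynamic_herg = dynamic_herg_fit(
                     cmax / ((0.6 / (1 - 0.6))^(1 / 1)), 1, 1))
  expect_equal(dynamic_bnet(d)$bnet, 60 - 25 - 5, tolerance = 1e-9)
})

test_that("panel scoring sorts by risk and breaks ties by name", {
  mk <- function(name, block) {
    drug_record(name, cmax_free = 0.2,
                fits = list(IKr = hill_fit(
                  1 / ((block / (100 - block))^(1 / 1)), 1)))
  }
  p <- drug_panel(list(mk("alpha", 45), mk("gamma", 1e-6), mk("beta", 50)))
  df <- bnet_panel(p, 5)
  expect_identical(df$drug, c("beta", "alpha", "gamma"))

  tie <- drug_panel(list(mk("zeta", 30), mk("eta", 30)))
  expect_identical(bnet_panel(tie, 5)$drug, c("eta", "zeta"))

  single <- drug_panel(list(mk("only", 10)))
  expect_identical(nrow(bnet_panel(single, 5)), 1L)
})

test_that("unscorable drugs abort strictly or are skipped leniently", {
  p <- drug_panel(list(
    drug_record("ok", cmax_free = 1, fits = list(IKr = hill_fit(1, 1))),
    drug_record("nocmax", fits = list(IKr = hill_fit(1, 1)))))
  expect_error(bnet_panel(p, 5), "cmax_free")
  expect_warning(df <- bnet_panel(p, 5, lenient = TRUE), "nocmax")
  expect_identical(df$drug, "ok")

  empty <- drug_panel(list(drug_record("nocmax",
                                       fits = list(IKr = hill_fit(1, 1)))))
  expect_warning(expect_warning(df <- bnet_panel(empty, 5, lenient = TRUE),
                                "skipped"), "no scorable")
  expect_identical(nrow(df), 0L)
})
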