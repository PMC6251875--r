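# Response transforms, normalization, MLR + LOO Q2 against brute-force
# oracles, subset search, published models and prediction.

test_that("K_m and activity transforms are exact and invertible", {
  expect_equal(km_to_pkm(100), 4.0)
  expect_equal(km_to_pkm(1), 6.0)
  expect_error(km_to_pkm(0), "positive")
  x <- c(0.5, 3, 170, 9999)
  expect_equal(pkm_to_km(km_to_pkm(x)), x, tolerance = 1e-12)
  expect_equal(activity_to_log(100), 2.0)
  expect_equal(activity_to_log(1), 0.0)
  expect_error(activity_to_log(-1), "positive")
  # strictly decreasing in K_m / increasing in activity
  expect_true(all(diff(km_to_pkm(sort(x))) < 0))
  expect_true(all(diff(activity_to_log(sort(x))) > 0))
})

test_that("normalization is a proper z-score with reusable parameters", {
  d <- gen_linear_dataset(40, c(a = 1, b = 2), noise_sd = 0.5, seed = 8)
  nd <- normalize_descriptors(d, cols = c("a", "b", "decoy1"))
  for (cl in c("a", "b", "decoy1")) {
    expect_lt(abs(mean(nd[[cl]])), 1e-12)
    expect_equal(sd(nd[[cl]]), 1, tolerance = 1e-12)
  }
  # renormalizing a normalized table is the identity
  nd2 <- normalize_descriptors(nd, cols = c("a", "b"))
  expect_equal(nd2$a, nd$a, tolerance = 1e-12)
  # external row via stored parameters matches the hand computation
  p <- norm_params(nd)
  ext <- tibble::tibble(a = 3, b = -1, decoy1 = 0)
  next_ <- normalize_descriptors(ext, params = p)
  pa <- p[p$column == "a", ]
  expect_equal(next_$a, (3 - pa$mean) / pa$sd, tolerance = 1e-12)
  # constant column is a named error
  d$const <- 5
  expect_error(normalize_descriptors(d, cols = c("a", "const")), "const")
})

test_that("fit_mlr equals the closed-form normal-equation solution", {
  d <- gen_linear_dataset(60, c(a = 2, b = -1, c = 0.5), noise_sd = 0.3,
                          seed = 12)
  m <- fit_mlr(d, "response", c("a", "b", "c"))
  beta <- normal_equation_fit(as.matrix(d[c("a", "b", "c")]), d$response)
  expect_equal(m$intercept, unname(beta[1]), tolerance = 1e-10)
  expect_equal(unname(m$coefficients), unname(beta[-1]), tolerance = 1e-10)
  expect_true(m$metrics$r_squared >= 0 && m$metrics$r_squared <= 1)
  expect_lte(m$metrics$q_squared, m$metrics$r_squared + 1e-9)
  # contract checks
  expect_error(fit_mlr(d, "response", c("a", "b", "c", "decoy1")), "max_k")
  d$dup <- d$a
  expect_error(fit_mlr(d, "response", c("a", "dup")), "collinear")
  expect_error(fit_mlr(d[1:3, ], "response", c("a", "b", "c")), "n >")
})

test_that("LOO Q2 equals the brute-force n-refit oracle", {
  for (seed in c(2, 7, 19)) {
    d <- gen_linear_dataset(25, c(a = 1.2, b = -0.4), noise_sd = 0.4,
                            seed = seed)
    q2 <- loo_q2(d, "response", c("a", "b"))
    expect_equal(q2, brute_force_q2(d, "response", c("a", "b")),
                 tolerance = 1e-10)
  }
  # noiseless: PRESS = 0 so Q2 = 1
  d0 <- gen_linear_dataset(15, c(a = 3), intercept = 2, noise_sd = 0,
                           seed = 4)
  expect_equal(loo_q2(d0, "response", "a"), 1, tolerance = 1e-10)
})

test_that("Q2 never exceeds R2 (PRESS >= RSS) across random tables", {
  set.seed(100)
  for (k in 1:100) {
    n <- sample(10:40, 1)
    d <- tibble::tibble(x1 = rnorm(n), x2 = rnorm(n),
                        response = rnorm(n))
    m <- fit_mlr(d, "response", c("x1", "x2"))
    expect_lte(m$metrics$q_squared, m$metrics$r_squared + 1e-9)
  }
})

test_that("subset search matches exhaustive enumeration and finds planted pairs", {
  d <- gen_linear_dataset(60, c(a = 1.5, b = -0.9), noise_sd = 0.05,
                          n_decoys = 8, seed = 21)
  res <- subset_search(d, "response", max_k = 2, criterion = "q2",
                       exclude = "id")
  # brute-force enumeration oracle over the same subsets
  cands <- sort(setdiff(names(d), c("id", "response")))
  subsets <- c(as.list(cands), utils::combn(cands, 2, simplify = FALSE))
  oracle_q2 <- vapply(subsets, function(s) loo_q2(d, "response", s),
                      numeric(1))
  best_oracle <- subsets[[which.max(oracle_q2)]]
  expect_equal(res$descriptors[1], paste(best_oracle, collapse = " + "))
  expect_equal(max(oracle_q2), res$q_squared[1], tolerance = 1e-12)
  # the planted pair ranks first
  expect_equal(res$descriptors[1], "a + b")
  # trivial case: x1 identical to y
  d2 <- tibble::tibble(x1 = 1:10 + 0, x2 = rnorm(10), y = 1:10 + 0)
  r2 <- subset_search(d2, "y", max_k = 1)
  expect_equal(r2$descriptors[1], "x1")
  expect_error(subset_search(gen_linear_dataset(40, c(a = 1), n_decoys = 30,
                                                seed = 1),
                             "response", exclude = "id"),
               "25")
})

test_that("the seven published models carry their printed coefficients", {
  m5 <- published_model(5)
  expect_equal(m5$intercept, 4.43)
  expect_equal(unname(m5$coefficients["IP"]), -2.93)
  expect_equal(m5$response, "pkm")
  m6 <- published_model(6)
  expect_equal(m6$intercept, 2.69)
  expect_equal(unname(m6$coefficients[c("accptHB", "IP", "E_Solv_PBF")]),
               c(1.99, -2.57, 1.51))
  m7 <- published_model(7)
  expect_equal(m7$intercept, 3.04)
  expect_equal(unname(m7$coefficients[c("FISA", "E_o_expt", "Vol/SASA")]),
               c(-1.14, -1.79, 3.98))
  m1 <- published_model(1)
  expect_equal(m1$intercept, 1.38)
  expect_equal(unname(m1$coefficients[c("QPlogPo/w", "QPlogS", "ESP_max")]),
               c(1.36, 0.88, -0.97))
  expect_equal(published_model(2)$intercept, 3.6)
  expect_equal(unname(published_model(3)$coefficients["EA"]), 1.00)
  expect_equal(unname(published_model(4)$coefficients["Vol/SASA"]), 1.91)
  expect_error(published_model(8), "1..7")
})

test_that("prediction applies normalization and reports trends", {
  m5 <- published_model(5)
  id_params <- tibble::tibble(column = "IP", mean = 0, sd = 1)
  # all-zero normalized descriptors return the printed intercept
  expect_equal(predict(m5, tibble::tibble(IP = 0),
                       norm_ref = id_params)$.pred, 4.43)
  expect_equal(predict(m5, tibble::tibble(IP = 1),
                       norm_ref = id_params)$.pred, 4.43 - 2.93)
  # missing descriptor and missing normalization are contract errors
  expect_error(predict(published_model(7), tibble::tibble(FISA = 1)),
               "E_o_expt")
  expect_error(predict(m5, tibble::tibble(IP = 1)), "norm_ref")
  # noiseless synthetic data generated from the model: trend R2 = 1
  set.seed(5)
  ref <- tibble::tibble(IP = rnorm(30, 8, 1))
  newd <- tibble::tibble(IP = rnorm(10, 8, 1))
  z <- (newd$IP - mean(ref$IP)) / sd(ref$IP)
  newd$pkm <- 4.43 - 2.93 * z
  pr <- predict(m5, newd, norm_ref = ref)
  expect_equal(trend_stats(pr)$r_squared, 1, tolerance = 1e-12)
  expect_equal(pr$.pred, newd$pkm, tolerance = 1e-12)
})

test_that("normalized-model predictions are scale-equivariant", {
  m6 <- published_model(6)
  set.seed(9)
  ref <- tibble::tibble(accptHB = rpois(20, 3) + 0,
                        IP = rnorm(20, 8, 1),
                        E_Solv_PBF = rnorm(20, -10, 3))
  newd <- ref[1:5, ]
  p1 <- predict(m6, newd, norm_ref = ref)$.pred
  # multiply a raw descriptor column by a constant everywhere
  ref2 <- ref; newd2 <- newd
  ref2$IP <- ref2$IP * 50; newd2$IP <- newd2$IP * 50
  p2 <- predict(m6, newd2, norm_ref = ref2)$.pred
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("adding a pure-noise descriptor cannot raise Q2 on average", {
  set.seed(77)
  wins <- 0
  for (k in 1:30) {
    d <- gen_linear_dataset(30, c(a = 1), noise_sd = 0.5, seed = 1000 + k)
    m1 <- fit_mlr(d, "response", "a")
    m2 <- fit_mlr(d, "response", c("a", "decoy1"))
    expect_gte(m2$metrics$r_squared, m1$metrics$r_squared - 1e-9)
    if (m2$metrics$q_squared > m1$metrics$q_squared) wins <- wins + 1
  }
  expect_lt(wins, 15)  # noise helps Q2 in well under half the trials
})

test_that("model serialization round-trips through JSON", {
  d <- gen_linear_dataset(30, c(a = 1.5, b = -0.7), noise_sd = 0.1, seed = 2)
  m <- fit_mlr(d, "response", c("a", "b"), normalize = TRUE)
  f <- withr::local_tempfile(fileext = ".json")
  write_qsar_model(m, f, data_hash = "abc")
  back <- read_qsar_model(f)
  expect_equal(back$intercept, m$intercept)
  expect_equal(back$coefficients, m$coefficients)
  expect_equal(back$metrics$r_squared, m$metrics$r_squared)
  p1 <- predict(m, d)$.pred
  p2 <- predict(back, d)$.pred
  expect_equal(p1, p2, tolerance = 1e-12)
  # published models survive the round trip including the normalization flag
  f2 <- withr::local_tempfile(fileext = ".json")
  write_qsar_model(published_model(5), f2)
  b5 <- read_qsar_model(f2)
  expect_error(predict(b5, tibble::tibble(IP = 1)), "norm_ref")
})

test_that("tidy and glance return the broom-style views", {
  m <- published_model(6)
  td <- tidy(m)
  expect_equal(td$term[1], "(Intercept)")
  expect_equal(td$estimate[1], 2.69)
  expect_equal(nrow(td), 4)
  gl <- glance(m)
  expect_equal(gl$r_squared, 0.77)
  expect_equal(gl$q_squared, 0.66)
  expect_match(gl$provenance, "published model 6")
})
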