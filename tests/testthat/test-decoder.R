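test_that("precomputed state handles degenerate priors and matches determinant oracle", {
  inst <- random_instance(p = 4, q = 5, C = 2, seed = 1)
  # zero prior covariance: U = I, Q = 0, logdet 0
  inst$prior$covariances[[1]] <- matrix(0, 4, 4)
  st <- precompute_state(inst$model, inst$prior)
  expect_equal(st$U[[1]], diag(4))
  expect_equal(st$Q[[1]], matrix(0, 4, 4))
  expect_equal(st$logdet_U[1], 0)
  # huge noise (D -> 0): U -> I for every cluster
  m2 <- inst$model
  m2$sigma2 <- rep(1e12, 5)
  st2 <- precompute_state(m2, inst$prior)
  expect_equal(st2$U[[2]], diag(4), tolerance = 1e-9)
  # log det U_c against an independent eigenvalue computation
  st3 <- precompute_state(inst$model, inst$prior)
  M <- diag(4) + inst$prior$covariances[[2]] %*% st3$D
  ev <- eigen(M, only.values = TRUE)$values
  expect_lt(abs(st3$logdet_U[2] + sum(log(Re(ev)))), 1e-9)
  expect_lt(max(abs(st3$D - t(st3$D))), 1e-10)
  expect_lt(max(abs(st3$Q[[2]] - t(st3$Q[[2]]))), 1e-8)
})

test_that("response projection matches the elementwise definition", {
  inst <- random_instance(p = 5, q = 7, C = 1, seed = 2)
  f <- transform_response(inst$model, inst$y)
  oracle <- numeric(5)
  for (i in 1:5) for (j in 1:7)
    oracle[i] <- oracle[i] + inst$B[i, j] * inst$y[j] / inst$sigma2[j]
  expect_equal(f, oracle, tolerance = 1e-12)
  expect_equal(transform_response(inst$model, rep(0, 7)), rep(0, 5))
  m <- inst$model
  m$sigma2 <- rep(1, 7)
  expect_equal(transform_response(m, inst$y), drop(inst$B %*% inst$y),
               tolerance = 1e-12)
  expect_error(transform_response(inst$model, rnorm(3)), "length")
})

test_that("posterior mean equals the information-form solution on full-rank priors", {
  for (s in 1:20) {
    inst <- random_instance(p = 3, q = 5, C = 2, seed = 100 + s)
    st <- precompute_state(inst$model, inst$prior)
    f <- transform_response(inst$model, inst$y)
    for (ci in 1:2) {
      R <- inst$prior$covariances[[ci]]
      m <- inst$prior$means[ci, ]
      oracle <- solve(solve(R) + st$D, solve(R, m) + f)
      expect_equal(posterior_mean(st, f, ci), drop(oracle), tolerance = 1e-8)
    }
  }
  # R = 0 and D = 0 both collapse to the prior mean
  inst <- random_instance(p = 4, q = 5, C = 1, seed = 3)
  inst$prior$covariances[[1]] <- matrix(0, 4, 4)
  st <- precompute_state(inst$model, inst$prior)
  f <- transform_response(inst$model, inst$y)
  expect_equal(posterior_mean(st, f, 1), inst$prior$means[1, ])
  inst2 <- random_instance(p = 4, q = 5, C = 1, seed = 4)
  m0 <- inst2$model
  m0$B <- matrix(0, 4, 5)             # D = 0, f_bar = 0
  st0 <- precompute_state(m0, inst2$prior)
  expect_equal(posterior_mean(st0, transform_response(m0, inst2$y), 1),
               inst2$prior$means[1, ])
})

test_that("responsibilities equal normalized marginal Gaussian densities", {
  for (s in 1:30) {
    p <- sample(2:4, 1)
    q <- sample(3:6, 1)
    C <- 3
    inst <- random_instance(p = p, q = q, C = C, seed = 200 + s)
    st <- precompute_state(inst$model, inst$prior)
    f <- transform_response(inst$model, inst$y)
    lr <- log_responsibilities(st, f, prior = inst$prior)
    # oracle: log P(c|y) from the marginal y | c ~ N(B'm_c, Sigma + B' R_c B)
    lm <- vapply(1:C, function(ci) {
      S <- diag(inst$sigma2) +
        t(inst$B) %*% inst$prior$covariances[[ci]] %*% inst$B
      log(inst$prior$weights[ci]) +
        dmvnorm_log(inst$y, drop(t(inst$B) %*% inst$prior$means[ci, ]), S)
    }, numeric(1))
    lm <- lm - max(lm) - log(sum(exp(lm - max(lm))))
    expect_equal(lr, lm, tolerance = 1e-8)
  }
})

test_that("responsibilities match numerical integration of the joint at p = 2", {
  inst <- random_instance(p = 2, q = 3, C = 2, seed = 5)
  st <- precompute_state(inst$model, inst$prior)
  f <- transform_response(inst$model, inst$y)
  r <- exp(log_responsibilities(st, f, prior = inst$prior))
  # dense-grid Riemann integration of int P(y|x) P(x|c) dx per cluster
  gx <- seq(-8, 8, length.out = 401)
  h <- gx[2] - gx[1]
  marg <- vapply(1:2, function(ci) {
    R <- inst$prior$covariances[[ci]]
    m <- inst$prior$means[ci, ]
    tot <- 0
    for (x1 in gx) {
      px <- vapply(gx, function(x2) {
        x <- c(x1, x2)
        exp(dmvnorm_log(inst$y, drop(t(inst$B) %*% x), diag(inst$sigma2)) +
              dmvnorm_log(x, m, R))
      }, numeric(1))
      tot <- tot + sum(px) * h * h
    }
    tot
  }, numeric(1))
  pq <- inst$prior$weights * marg
  expect_equal(r, pq / sum(pq), tolerance = 1e-3)
})

test_that("log responsibility normalization is a simplex and shift-invariant", {
  inst <- random_instance(p = 3, q = 4, C = 3, seed = 6)
  st <- precompute_state(inst$model, inst$prior)
  f <- transform_response(inst$model, inst$y)
  lr <- log_responsibilities(st, f, prior = inst$prior)
  expect_equal(sum(exp(lr)), 1, tolerance = 1e-12)
  shifted <- log_responsibilities(st, f,
                                  log_prior_weights = log(inst$prior$weights) + 57)
  expect_equal(lr, shifted, tolerance = 1e-10)
  # single cluster -> probability one; identical clusters -> exact halves
  inst1 <- random_instance(p = 3, q = 4, C = 1, seed = 7)
  st1 <- precompute_state(inst1$model, inst1$prior)
  expect_equal(log_responsibilities(st1, transform_response(inst1$model, inst1$y),
                                    prior = inst1$prior), 0)
  inst2 <- random_instance(p = 3, q = 4, C = 2, seed = 8)
  inst2$prior$means[2, ] <- inst2$prior$means[1, ]
  inst2$prior$covariances[[2]] <- inst2$prior$covariances[[1]]
  inst2$prior$weights <- c(0.5, 0.5)
  st2 <- precompute_state(inst2$model, inst2$prior)
  r2 <- exp(log_responsibilities(st2, transform_response(inst2$model, inst2$y),
                                 prior = inst2$prior))
  expect_identical(r2[1], r2[2])
  expect_error(log_responsibilities(st2, rep(0, 3),
                                    log_prior_weights = c(-Inf, -Inf)), "zero")
})

test_that("the never-inverted Q formulation obeys the push-through identity", {
  set.seed(9)
  for (s in 1:10) {
    R <- random_psd(4)
    D <- random_psd(4)
    lhs <- solve(diag(4) + R %*% D) %*% R
    rhs <- R %*% solve(diag(4) + D %*% R)
    expect_lt(max(abs(lhs - rhs)), 1e-8)
  }
})

test_that("reconstruction weighting: hard winner vs tempered average", {
  inst <- random_instance(p = 4, q = 6, C = 3, seed = 10)
  st <- precompute_state(inst$model, inst$prior)
  f <- transform_response(inst$model, inst$y)
  resp <- c(0.2, 0.5, 0.3)
  hard <- reconstruct(st, f, resp, temperature = "hard")
  expect_identical(hard$winner, 2L)
  expect_equal(hard$reconstruction, posterior_mean(st, f, 2))
  expect_identical(reconstruct(st, f, c(0.9, 0.1, 0), "hard")$winner, 1L)
  # T = 1: weights equal responsibilities; loop oracle
  t1 <- reconstruct(st, f, resp, temperature = 1)
  oracle <- resp[1] * posterior_mean(st, f, 1) +
    resp[2] * posterior_mean(st, f, 2) + resp[3] * posterior_mean(st, f, 3)
  expect_equal(t1$reconstruction, oracle, tolerance = 1e-10)
  # small T approaches the hard limit
  t001 <- reconstruct(st, f, resp, temperature = 0.01)
  expect_equal(t001$reconstruction, hard$reconstruction, tolerance = 1e-6)
  expect_error(reconstruct(st, f, resp, temperature = -1), "positive")
  # single cluster: x* = n_1 at any temperature
  inst1 <- random_instance(p = 4, q = 6, C = 1, seed = 11)
  st1 <- precompute_state(inst1$model, inst1$prior)
  f1 <- transform_response(inst1$model, inst1$y)
  expect_equal(reconstruct(st1, f1, 1, "hard")$reconstruction,
               reconstruct(st1, f1, 1, 5)$reconstruction)
})

test_that("letter probabilities marginalize the label table", {
  r <- c(0.5, 0.3, 0.2)
  expect_equal(letter_probability(r, diag(3)), r)
  lt_unif <- matrix(1 / 2, 3, 2)
  expect_equal(letter_probability(r, lt_unif), c(0.5, 0.5))
  lt <- rbind(c(0.75, 0.25), c(0.1, 0.9), c(0.5, 0.5))
  expect_equal(letter_probability(r, lt),
               c(0.5 * 0.75 + 0.3 * 0.1 + 0.2 * 0.5,
                 0.5 * 0.25 + 0.3 * 0.9 + 0.2 * 0.5))
  expect_equal(sum(letter_probability(r, lt)), 1, tolerance = 1e-12)
})

test_that("batch decoding equals the single-trial path and is order-equivariant", {
  study <- default_study()
  sup <- build_supervised_prior(study$bundle$prior)
  sub <- response_set(study$bundle$test_responses$data[1:6, , drop = FALSE])
  out <- decode_batch(study$model, sup, sub)
  one <- decode_batch(study$model, sup,
                      response_set(sub$data[3, , drop = FALSE]))
  expect_equal(out$reconstructions[3, ], one$reconstructions[1, ])
  expect_identical(out$winners[3], one$winners[1])
  perm <- c(4, 1, 6, 2, 5, 3)
  outp <- decode_batch(study$model, sup, response_set(sub$data[perm, ]))
  expect_equal(outp$reconstructions, out$reconstructions[perm, ])
  expect_identical(outp$winners, out$winners[perm])
  expect_equal(rowSums(out$responsibilities), rep(1, 6), tolerance = 1e-10)
  expect_equal(rowSums(out$letter_probs), rep(1, 6), tolerance = 1e-10)
})

test_that("with uninformative data responsibilities fall back to the prior weights", {
  inst <- random_instance(p = 3, q = 4, C = 3, seed = 12)
  m <- inst$model
  m$sigma2 <- rep(1e14, 4)
  st <- precompute_state(m, inst$prior)
  f <- transform_response(m, inst$y)
  r <- exp(log_responsibilities(st, f, prior = inst$prior))
  expect_equal(r, inst$prior$weights, tolerance = 1e-6)
  for (ci in 1:3)
    expect_equal(posterior_mean(st, f, ci), inst$prior$means[ci, ],
                 tolerance = 1e-6)
})
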