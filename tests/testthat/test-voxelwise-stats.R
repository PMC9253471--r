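make_baseline <- function(n, seed) {
  sim <- generate_cohort(cohort_sim_config(n_subjects = n, seed = seed))
  sim$cohort[sim$cohort$timepoint == "baseline", ]
}

test_that("the design matrix expands phenotype x treatment combinations", {
  base <- make_baseline(120L, 61L)
  des <- build_design(base)
  expect_equal(qr(des$X)$rank, ncol(des$X))
  expect_true("snfl_z" %in% colnames(des$X))
  # observed combinations generate columns; the first level is the reference
  n_combo <- length(unique(interaction(base$phenotype, base$treatment,
                                       drop = TRUE)))
  expect_equal(sum(grepl("^combo_", colnames(des$X))), n_combo - 1L)
  # an absent combination contributes no column
  base2 <- base[!(base$phenotype == "PMS" &
                    base$treatment == "highly-effective"), ]
  des2 <- build_design(base2)
  expect_false("combo_PMS:highly-effective" %in% colnames(des2$X))
  expect_equal(qr(des2$X)$rank, ncol(des2$X))
  # continuous-only designs carry no dummy columns
  des3 <- build_design(data.frame(snfl = rlnorm(30, 2, 0.5),
                                  age = rnorm(30, 40, 9)))
  expect_equal(colnames(des3$X), c("(Intercept)", "snfl_z", "age_z"))
})

test_that("per-voxel t-statistics match a hand OLS computation", {
  # printed 6-subject toy design, 1 voxel
  X <- cbind(1, c(-1.2, -0.5, 0.1, 0.4, 0.9, 0.3))
  y <- matrix(c(0.3, 0.1, 0.5, 0.8, 1.2, 0.4), ncol = 1)
  beta <- ols_oracle(X, y[, 1])
  res <- y[, 1] - X %*% beta
  s2 <- sum(res^2) / (6 - 2)
  t_hand <- beta[2] / sqrt(s2 * solve(crossprod(X))[2, 2])
  tmap <- glm_tmap(y, X, c(0, 1))
  expect_equal(as.numeric(tmap), as.numeric(t_hand), tolerance = 1e-12)
  expect_equal(as.numeric(tmap),
               summary(lm(y[, 1] ~ X[, 2]))$coefficients[2, 3],
               tolerance = 1e-10)
  # a response equal to the regressor has no residual: flagged, t = 0
  y2 <- cbind(y, X[, 2])
  t2 <- glm_tmap(y2, X, c(0, 1))
  expect_equal(attr(t2, "degenerate"), 2L)
  expect_equal(t2[2], 0)
})

test_that("null t-maps follow the Student-t distribution", {
  set.seed(71)
  base <- make_baseline(50L, 71L)
  des <- build_design(base)
  Y <- matrix(rnorm(50 * 1000), 50)
  t <- glm_tmap(Y, des$X, des$contrast)
  dfree <- 50 - ncol(des$X)
  ks <- ks.test(t, pt, df = dfree)
  expect_gt(ks$p.value, 0.01)
})

test_that("TFCE matches closed forms on singleton and plateau inputs", {
  cfg <- tfce_config()
  d <- c(8, 8, 8)
  mask <- array(1L, d)
  # all-zero map stays zero
  expect_true(all(tfce(array(0, d), mask) == 0))
  # isolated voxel of height 1.3: e(h) = 1 for every level
  s <- array(0, d); s[4, 4, 4] <- 1.3
  e <- tfce(s, mask, cfg)
  hs <- seq(0.1, 1.3, by = 0.1)
  expect_equal(e[4, 4, 4], sum(hs^2 * 0.1), tolerance = 1e-10)
  expect_true(all(e[-(4 + 8 * 3 + 64 * 3)] == 0))
  # flat plateau of 12 voxels at height 0.7: extent^0.5 scales every level
  s2 <- array(0, d); s2[2:5, 2:4, 3] <- 0     # define region
  s2[2:4, 2:5, 3] <- 0.7
  n_pl <- sum(s2 > 0)
  e2 <- tfce(s2, mask, cfg)
  hs2 <- seq(0.1, 0.7, by = 0.1)
  expect_equal(unique(round(e2[s2 > 0], 12)),
               round(n_pl^0.5 * sum(hs2^2 * 0.1), 12))
  # negative lobes are enhanced on the negated map with sign preserved
  s3 <- s; s3[6, 6, 6] <- -1.3
  e3 <- tfce(s3, mask, cfg)
  expect_equal(e3[6, 6, 6], -e[4, 4, 4], tolerance = 1e-12)
})

test_that("TFCE is monotone under uniform scaling and matches the oracle", {
  skip_if_not_installed("igraph")
  set.seed(5)
  d <- c(8, 8, 8)
  mask <- array(rbinom(prod(d), 1, 0.9), d)
  s <- array(pmax(rnorm(prod(d), 0.5, 0.8), 0), d)
  cfg <- tfce_config()
  e1 <- tfce(s, mask, cfg)
  e2 <- tfce(2 * s, mask, cfg)
  expect_true(all(e2 - e1 >= -1e-12))
  orac <- tfce_oracle(s, mask)
  expect_equal(e1, orac, tolerance = 1e-6)
  # 6-connectivity separates diagonal neighbours the 26-case joins
  cfg6 <- tfce_config(connectivity = 6L)
  s4 <- array(0, d); s4[2, 2, 2] <- 1; s4[3, 3, 3] <- 1
  e26 <- tfce(s4, mask = array(1L, d), cfg)
  e6 <- tfce(s4, mask = array(1L, d), cfg6)
  expect_gt(e26[2, 2, 2], e6[2, 2, 2])
})

test_that("permutation p-values match the exhaustive oracle at n = 5", {
  set.seed(15)
  n <- 5L
  X <- cbind(1, rnorm(n))
  mask <- array(1L, c(2, 2, 1))
  Y <- matrix(rnorm(n * 4), n, 4)
  expect_message(
    res <- permutation_fwer(Y, X, c(0, 1), mask, n_perm = 5000L, seed = 3L),
    "exhaustive")
  expect_equal(res$n_perm, 120L)
  expect_true(res$exhaustive)
  # independent enumeration of all relabelings (Heap's algorithm)
  P <- perms_oracle(n)
  Z <- X[, 1, drop = FALSE]
  Hz <- Z %*% solve(crossprod(Z)) %*% t(Z)
  Ez <- Y - Hz %*% Y
  cfgt <- tfce_config()
  tf <- function(tv) {
    vol <- array(0, dim(mask)); vol[mask != 0] <- tv
    e <- tfce(vol, mask, cfgt)
    e[mask != 0]
  }
  maxes <- apply(P, 1, function(pp) {
    tb <- glm_tmap(Hz %*% Y + Ez[pp, ], X, c(0, 1))
    max(pmax(tf(tb), 0))
  })
  obs <- tf(glm_tmap(Y, X, c(0, 1)))
  p_orac <- vapply(pmax(obs, 0), function(o)
    (1 + sum(maxes >= o)) / (1 + length(maxes)), numeric(1))
  expect_equal(res$fwer_p$positive, p_orac, tolerance = 1e-12)
})

test_that("permutation inference is deterministic given the seed", {
  set.seed(81)
  base <- make_baseline(20L, 81L)
  des <- build_design(base)
  mask <- array(1L, c(4, 4, 2))
  Y <- matrix(rnorm(20 * 32), 20, 32)
  r1 <- permutation_fwer(Y, des$X, des$contrast, mask, n_perm = 200L,
                         seed = 11L)
  r2 <- permutation_fwer(Y, des$X, des$contrast, mask, n_perm = 200L,
                         seed = 11L)
  expect_identical(r1$fwer_p, r2$fwer_p)
  expect_identical(r1$null_max, r2$null_max)
  expect_true(all(r1$fwer_p$positive > 0 & r1$fwer_p$positive <= 1))
})

test_that("a planted focal effect is recovered at its location", {
  set.seed(91)
  n <- 60L
  base <- make_baseline(n, 91L)
  des <- build_design(base)
  d <- c(6, 6, 3)
  mask <- array(1L, d)
  V <- prod(d)
  Y <- matrix(rnorm(n * V, 0, 0.3), n, V)
  # strong NfL effect in a 2x2x1 cluster (voxels 1,2,7,8 in array order)
  clust <- c(1, 2, 7, 8)
  for (v in clust) Y[, v] <- Y[, v] + 1.5 * zscore(base$snfl)
  res <- permutation_fwer(Y, des$X, des$contrast, mask, n_perm = 300L,
                          seed = 5L)
  expect_true(all(res$significant$positive[clust]))
  expect_lt(mean(res$significant$positive[-clust]), 0.1)
  expect_true(!any(res$significant$negative[clust]))
})
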