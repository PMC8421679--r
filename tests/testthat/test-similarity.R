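test_that("tanimoto matches hand-worked cases", {
  L <- 166
  mk <- function(bits) {
    v <- numeric(L)
    v[bits] <- 1
    v
  }
  fps <- fingerprint_set(
    c("same1", "same2", "dis1", "dis2", "ab", "ac", "zero"),
    rbind(mk(c(3, 9)), mk(c(3, 9)), mk(1:4), mk(5:8),
          mk(c(1, 2)), mk(c(1, 3)), mk(integer(0))))
  S <- tanimoto_matrix(fps)$S
  expect_equal(S["same1", "same2"], 1)
  expect_equal(S["dis1", "dis2"], 0)
  expect_equal(S["ab", "ac"], 1 / 3) # intersection 1, union 3
  # 0/0 convention: zero fingerprint is similar to nothing but itself
  expect_equal(S["zero", "ab"], 0)
  expect_equal(S["zero", "zero"], 1)
})

test_that("tanimoto equals the exhaustive bit-counting oracle", {
  set.seed(11)
  for (rep in 1:3) {
    fps <- random_fingerprints(6)
    S <- tanimoto_matrix(fps)$S
    for (i in 1:6) {
      for (j in 1:6) {
        expect_identical(S[i, j],
                         if (i == j) 1 else
                           oracle_tanimoto(fps$bits[i, ], fps$bits[j, ]))
      }
    }
  }
})

test_that("gip_bandwidth normalizes by the mean squared profile norm", {
  expect_equal(gip_bandwidth(rbind(c(1, 0), c(1, 1))), 2 / 3)
  expect_equal(gip_bandwidth(matrix(c(1, 1, 1, 1), 1)), 0.25)
  # exactly linear in gamma_prime
  P <- matrix(rbinom(30, 1, 0.5), 5)
  P[1, 1] <- 1
  expect_equal(gip_bandwidth(P, 2), 2 * gip_bandwidth(P, 1))
  expect_error(gip_bandwidth(matrix(0, 3, 4)), "degenerate profiles")
})

test_that("gip_kernel matches hand-worked cases and zero-profile policies", {
  K <- gip_kernel(rbind(c(1, 0), c(0, 1)))$S
  expect_equal(K[1, 2], exp(-2)) # gamma = 1, squared distance 2
  expect_equal(diag(K), c(p1 = 1, p2 = 1))

  P <- rbind(a = c(1, 1), b = c(0, 0), c = c(0, 0))
  expect_equal(gip_kernel(P, zero_profile_policy = "formula")$S["b", "c"], 1)
  z <- gip_kernel(P, zero_profile_policy = "zero")$S
  expect_equal(z["b", "c"], 0)
  expect_equal(diag(z), c(a = 1, b = 1, c = 1))
})

test_that("gip_kernel equals the scalar double-loop oracle", {
  set.seed(23)
  for (rep in 1:5) {
    n <- sample(2:8, 1)
    p <- sample(2:8, 1)
    P <- matrix(rbinom(n * p, 1, 0.5), n)
    if (all(P == 0)) P[1, 1] <- 1
    gp <- sample(c(0.5, 1, 2), 1)
    K <- gip_kernel(P, gamma_prime = gp)$S
    expect_lt(max(abs(K - oracle_gip(P, gp))), 1e-12)
  }
})

test_that("increasing gamma_prime never increases off-diagonal GIP entries", {
  set.seed(5)
  P <- matrix(rbinom(48, 1, 0.4), 8)
  P[1, 1] <- 1
  prev <- gip_kernel(P, gamma_prime = 0.5)$S
  for (gp in c(1, 2, 4)) {
    cur <- gip_kernel(P, gamma_prime = gp)$S
    off <- upper.tri(cur)
    expect_true(all(cur[off] <= prev[off] + 1e-15))
    prev <- cur
  }
})

test_that("fusion is a convex combination, exactly linear in alpha", {
  set.seed(9)
  n <- 6
  mk <- function() {
    S <- matrix(runif(n * n), n)
    S <- (S + t(S)) / 2
    diag(S) <- 1
    similarity_matrix(letters[1:n], S)
  }
  a <- mk()
  b <- mk()
  expect_identical(fuse_drug(a, b, alpha = 0)$S, a$S)
  expect_identical(fuse_drug(a, b, alpha = 1)$S, b$S)

  s0 <- fuse_drug(a, b, 0)$S
  s1 <- fuse_drug(a, b, 1)$S
  for (alpha in c(0.25, 0.5, 0.9)) {
    expect_equal(fuse_drug(a, b, alpha)$S, s0 + alpha * (s1 - s0),
                 tolerance = 1e-14)
  }

  # the 0.5:0.5 default mixes entries to their midpoint
  a$S[1, 2] <- a$S[2, 1] <- 0.2
  b$S[1, 2] <- b$S[2, 1] <- 0.4
  expect_equal(fuse_drug(a, b)$S[1, 2], 0.3)
  expect_equal(fuse_target(a, b, 0.5)$S[1, 2], 0.3)

  c_ids <- mk()
  c_ids$ids[2] <- "zz"
  rownames(c_ids$S)[2] <- colnames(c_ids$S)[2] <- "zz"
  expect_error(fuse_drug(a, c_ids), "symmetric difference.*(b|zz)")
})

test_that("similarity outputs satisfy the container invariants", {
  set.seed(31)
  d <- generate_synthetic(synth_config(m = 12, n = 15, k = 8, seed = 3))
  sims <- similarity_pipeline(d$interactions, d$fingerprints, d$diseases)
  for (S in lapply(sims, `[[`, "S")) {
    expect_lt(max(abs(S - t(S))), 1e-12)
    expect_true(all(S >= 0 & S <= 1))
    expect_equal(unname(diag(S)), rep(1, nrow(S)))
  }
})

test_that("similarity_pipeline handles missing fingerprints per policy", {
  d <- generate_synthetic(synth_config(m = 6, n = 8, k = 4, seed = 4))
  fps <- d$fingerprints
  partial <- fingerprint_set(fps$drug_ids[-1], fps$bits[-1, , drop = FALSE])
  expect_error(
    similarity_pipeline(d$interactions, partial, d$diseases),
    "no fingerprint for drug")
  expect_warning(
    sims <- similarity_pipeline(d$interactions, partial, d$diseases,
                                allow_missing_fingerprints = TRUE),
    "all-zero fingerprints")
  expect_equal(sims$sim_chem$S[1, 2], 0) # zero fingerprint: no similarity
})

test_that("targets without disease data carry zero profiles into fusion", {
  d <- generate_synthetic(synth_config(m = 6, n = 8, k = 4, seed = 5))
  # drop all disease rows: with policy "zero" the disease kernel is identity,
  # so off-diagonal fused = (1 - alpha) * K_gip_t
  sims <- similarity_pipeline(d$interactions, d$fingerprints, NULL,
                              zero_profile_policy = "zero")
  off <- upper.tri(sims$sim_tar$S)
  expect_equal(sims$sim_tar$S[off], 0.5 * sims$k_gip_t$S[off],
               tolerance = 1e-14)
})
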