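test_that("per-sample and mean neighborhood entropies behave on the worked example", {
  dt <- example_table()
  nb <- neighborhoods(dt, delta = 0.3)
  expect_equal(neighborhood_entropy(nb, 1), 2)           # singleton: -log2(1/4)
  expect_equal(neighborhood_entropy(nb), c(2, 1, 1, 2))
  expect_equal(mean_neighborhood_entropy(nb), 1.5)

  # saturated neighborhoods carry no information
  sat <- neighborhoods(normalize_minmax(random_table(5, 1, seed = 3)), delta = 1)
  expect_equal(mean_neighborhood_entropy(sat), 0)

  # bounds: 1 <= |n(x)| <= n
  for (seed in 1:6) {
    dt2 <- random_table(7, 3, seed = seed)
    nb2 <- neighborhoods(dt2, delta = withr::with_seed(seed, runif(1)))
    h <- neighborhood_entropy(nb2)
    expect_true(all(h >= 0 & h <= log2(7)))
  }
})

test_that("identical neighborhood structures give identical entropies", {
  dt <- example_table()
  nb_full <- neighborhoods(dt, delta = 0.3)
  nb_ac <- neighborhoods(dt, c("a", "c"), delta = 0.3)
  expect_equal(mean_neighborhood_entropy(nb_ac), mean_neighborhood_entropy(nb_full))
  expect_equal(joint_entropy(dt, c("a", "c"), delta = 0.3),
               joint_entropy(dt, delta = 0.3))
  expect_equal(nrh(dt, c("a", "c"), delta = 0.3), nrh(dt, delta = 0.3))
})

test_that("joint entropy matches hand values and is monotone in the subset", {
  dt <- example_table()
  # every class-constrained neighborhood is a singleton at delta = 0.3
  expect_equal(joint_entropy(dt, delta = 0.3), 2)

  one <- decision_table(data.frame(x = 0.5, lab = "A"))
  expect_equal(joint_entropy(one, delta = 0.5), 0)

  for (seed in 1:15) {
    dt2 <- random_table(9, 5, n_classes = 2, seed = seed)
    withr::with_seed(seed + 50, {
      delta <- runif(1, 0.05, 0.8)
      P <- sample(5, sample(2:5, 1))
      Q <- sample(P, sample(length(P) - 1, 1))
    })
    expect_lte(joint_entropy(dt2, Q, delta = delta),
               joint_entropy(dt2, P, delta = delta) + 1e-12)
    expect_equal(joint_entropy(dt2, P, delta = delta),
                 oracle_joint_entropy(tbl_X(dt2), tbl_y(dt2), P, delta))
  }
})

test_that("NRH reproduces the worked-example values", {
  dt <- example_table()
  expect_equal(nrh(dt, delta = 0.3), 2 * log2(4 / 3), tolerance = 1e-12)
  expect_equal(round(nrh(dt, delta = 0.3), 2), 0.83)
  expect_equal(round(nrh(dt, "c", delta = 0.3), 4), 0.3219)
  expect_equal(nrh(dt, c("a", "b"), delta = 0.3), 0.6226, tolerance = 1e-4)
  # empty subset with two classes: every class fully rough, NRH = 0
  expect_equal(nrh(dt, character(0), delta = 0.3), 0)
})

test_that("internal significances match the worked example and duplicate logic", {
  dt <- example_table()
  expect_equal(round(sig_inner(dt, "a", delta = 0.3), 4), 0.5081)
  expect_equal(sig_inner(dt, "b", delta = 0.3), 0)
  expect_equal(round(sig_inner(dt, "c", delta = 0.3), 4), 0.2075)
  expect_error(sig_inner(dt, "a", attributes = c("b", "c"), delta = 0.3),
               "not in the subset")

  # a constant column contributes nothing to any distance, so it is never
  # individually significant; a clone doubles its coordinate's weight and is
  # therefore only guaranteed nonnegative
  df <- as.data.frame(random_table(8, 3, seed = 21))
  df$flat <- 0.4
  df$v1_clone <- df$v1
  aug <- decision_table(df[c("v1", "v2", "v3", "flat", "v1_clone", "cls")],
                        decision = "cls")
  expect_equal(sig_inner(aug, "flat", delta = 0.25), 0)
  expect_gte(sig_inner(aug, "v1_clone", delta = 0.25), 0)
})

test_that("external significance is a nonnegative NRH gain that telescopes", {
  dt <- example_table()
  gain <- sig_outer(dt, "c", attributes = "a", delta = 0.3)
  expect_equal(gain, nrh(dt, c("a", "c"), delta = 0.3) - nrh(dt, "a", delta = 0.3))
  expect_equal(nrh(dt, c("a", "c"), delta = 0.3), 2 * log2(4 / 3), tolerance = 1e-12)
  expect_error(sig_outer(dt, "a", attributes = "a", delta = 0.3), "already")

  # a constant candidate leaves every distance unchanged and adds nothing
  df <- as.data.frame(random_table(8, 2, seed = 31))
  df$flat <- 0.7
  aug <- decision_table(df[c("v1", "v2", "flat", "cls")], decision = "cls")
  expect_equal(sig_outer(aug, "flat", attributes = c("v1", "v2"), delta = 0.3), 0)

  # telescoping along a greedy path from the empty set
  dt2 <- random_table(10, 4, seed = 41)
  path <- c(3L, 1L, 4L, 2L)
  total <- nrh(dt2, integer(0), delta = 0.3)
  B <- integer(0)
  for (a in path) {
    total <- total + sig_outer(dt2, a, attributes = B, delta = 0.3)
    B <- c(B, a)
  }
  expect_equal(total, nrh(dt2, delta = 0.3), tolerance = 1e-12)
})

test_that("NRH is nonnegative, monotone over nested chains, and oracle-exact", {
  for (seed in 1:15) {
    dt <- random_table(6, 4, n_classes = 2, seed = seed)
    delta <- withr::with_seed(seed + 60, runif(1, 0.05, 0.9))
    chain <- withr::with_seed(seed + 70, {
      full <- sample(4)
      list(integer(0), full[1], full[1:2], full[1:3], full)
    })
    vals <- vapply(chain, function(B) nrh(dt, B, delta = delta), numeric(1))
    expect_true(all(vals >= 0))
    expect_true(all(diff(vals) >= -1e-12))
    for (B in chain[-1]) {
      expect_equal(nrh(dt, B, delta = delta),
                   oracle_nrh(tbl_X(dt), tbl_y(dt), B, delta))
    }
  }
})

test_that("NRH limits: one class reduces to mean entropy; tiny radius gives log2 n", {
  for (seed in 1:6) {
    df <- as.data.frame(random_table(8, 3, seed = seed))
    df$cls <- "only"
    one <- decision_table(df, decision = "cls")
    delta <- withr::with_seed(seed, runif(1, 0.1, 0.9))
    expect_equal(nrh(one, delta = delta),
                 mean_neighborhood_entropy(neighborhoods(one, delta = delta)))

    dt <- random_table(8, 3, seed = seed + 500)
    D <- pairwise_distances(dt)
    tiny <- min(D[D > 0]) / 2
    expect_equal(nrh(dt, delta = tiny), log2(8))
  }
})

test_that("entropy profile assembles the family consistently", {
  dt <- example_table()
  ep <- entropy_profile(dt, delta = 0.3)
  expect_equal(ep$mean_entropy, 1.5)
  expect_equal(ep$joint_entropy, 2)
  expect_equal(ep$nrh, 2 * log2(4 / 3), tolerance = 1e-12)
  expect_equal(ep$per_sample[[1]], c(2, 1, 1, 2))
  expect_equal(ep$subset[[1]], c("a", "b", "c"))
})
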