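test_that("niche range takes per-substrate min, mean, max of the controls", {
  m <- rbind(r1 = c(s1 = 0.2, s2 = 0), r2 = c(s1 = 0.5, s2 = 0),
             r3 = c(s1 = 0.8, s2 = 0))
  rng <- niche_range(m)
  expect_equal(rng$lower, c(0.2, 0))
  expect_equal(rng$center, c(0.5, 0))
  expect_equal(rng$upper, c(0.8, 0))
  expect_equal(attr(rng, "n_control"), 3)

  same <- rbind(a = c(s1 = 1.1), b = c(s1 = 1.1))
  rng2 <- niche_range(same)
  expect_equal(rng2$lower, rng2$center)
  expect_equal(rng2$center, rng2$upper)

  expect_error(niche_range(m[1, , drop = FALSE]), "at least 2")
})

test_that("decomposition splits deviations at the control limits", {
  rng <- range_from(0.2, c(s1 = 0.5), 0.8)
  up <- niche_decompose(c(s1 = 1.1), rng)
  expect_equal(unname(up$intensification[1, 1]), 0.3)
  expect_equal(unname(up$expansion[1, 1]), 0.3)
  expect_equal(unname(up$narrowing[1, 1] + up$contraction[1, 1]), 0)

  down <- niche_decompose(c(s1 = 0.1), rng)
  expect_equal(unname(down$narrowing[1, 1]), 0.3)
  expect_equal(unname(down$contraction[1, 1]), 0.1)

  none <- niche_decompose(c(s1 = 0.5), rng)
  expect_equal(sum(vapply(none, sum, numeric(1))), 0)

  expect_error(niche_decompose(c(zz = 1), rng), "different substrate sets")
})

test_that("decomposition matches the interval-measure oracle", {
  set.seed(31)
  for (i in 1:40) {
    ctrl <- sort(runif(3, 0, 2))
    rng <- range_from(ctrl[1], c(s = ctrl[2]), ctrl[3])
    x <- runif(1, -0.5, 3)
    x <- max(0, x)
    d <- niche_decompose(c(s = x), rng)
    got <- vapply(d, function(m) unname(m[1, 1]), numeric(1))
    want <- oracle_decompose_one(x, ctrl[1], ctrl[2], ctrl[3], n = 20001)
    expect_equal(got, want[names(got)], tolerance = 5e-4)
  }
})

test_that("decomposition identity and one-sidedness hold on random draws", {
  set.seed(32)
  n <- 2000
  lower <- runif(n, 0, 1)
  center <- lower + runif(n, 0, 1)
  upper <- center + runif(n, 0, 1)
  x <- runif(n, 0, 3.5)
  names(x) <- paste0("s", 1:n)
  rng <- range_from(lower, setNames(center, names(x)), upper)
  d <- niche_decompose(x, rng)
  int <- d$intensification[1, ]; ex <- d$expansion[1, ]
  nar <- d$narrowing[1, ]; con <- d$contraction[1, ]
  expect_true(all(int >= 0 & ex >= 0 & nar >= 0 & con >= 0))
  expect_equal(unname(int + ex - nar - con), unname(x - center))
  expect_true(all((int + ex) * (nar + con) == 0))
  # expansion implies the within-range part is saturated, and vice versa
  expect_equal(unname(int[ex > 0]), unname((upper - center)[ex > 0]))
  expect_equal(unname(nar[con > 0]), unname((center - lower)[con > 0]))
})

test_that("increasing a response never lowers the gains or raises the losses", {
  set.seed(33)
  for (i in 1:200) {
    ctrl <- sort(runif(3, 0, 2))
    rng <- range_from(ctrl[1], c(s = ctrl[2]), ctrl[3])
    x1 <- runif(1, 0, 3)
    x2 <- x1 + runif(1, 0, 1)
    d1 <- niche_decompose(c(s = x1), rng)
    d2 <- niche_decompose(c(s = x2), rng)
    gain <- function(d) d$intensification[1, 1] + d$expansion[1, 1]
    loss <- function(d) d$narrowing[1, 1] + d$contraction[1, 1]
    expect_gte(gain(d2), gain(d1))
    expect_lte(loss(d2), loss(d1))
  }
})

test_that("control replicates never expand or contract their own range", {
  set.seed(34)
  ctrl <- rbind(c1 = rand_profile(), c2 = rand_profile(), c3 = rand_profile(),
                c4 = rand_profile())
  rng <- niche_range(ctrl)
  d <- niche_decompose(ctrl, rng)
  expect_equal(sum(d$expansion), 0)
  expect_equal(sum(d$contraction), 0)
  # the replicate attaining the maximum saturates intensification
  for (s in colnames(ctrl)) {
    top <- which.max(ctrl[, s])
    expect_equal(unname(d$intensification[top, s]),
                 unname(max(ctrl[, s]) - mean(ctrl[, s])))
  }
})

test_that("segment indices are percents of the sample's own activity", {
  rng <- range_from(rep(0.4, 31), setNames(rep(0.5, 31), codes31),
                    rep(0.6, 31))
  x <- setNames(rep(0.5, 31), codes31)
  d <- niche_decompose(x, rng)
  idx <- segment_indices(d, x)
  expect_equal(unlist(idx[1, segment_names()], use.names = FALSE),
               rep(0, 4))

  set.seed(35)
  for (i in 1:25) {
    prof <- rand_profile() + 0.01
    d <- niche_decompose(prof, rng)
    idx <- segment_indices(d, prof)
    lhs <- idx$intensification + idx$expansion - idx$narrowing - idx$contraction
    rhs <- 100 * (sum(prof) - sum(rng$center)) / sum(prof)
    expect_equal(lhs, rhs)
    expect_true(all(idx[, segment_names()] >= 0))
  }
  expect_error(segment_indices(d, setNames(rep(0, 31), codes31)),
               "zero-total")
})

test_that("functional alteration is the signed percent change vs control", {
  expect_equal(functional_alteration(50.7, 50.7), 0)
  expect_equal(functional_alteration(45.4, 50.7), 100 * (45.4 - 50.7) / 50.7)
  expect_equal(round(functional_alteration(45.4, 50.7), 2), -10.45)
  expect_equal(round(functional_alteration(54.2, 50.7), 2), 6.9)
  expect_error(functional_alteration(10, 0), "positive")
})

test_that("shared-with-control profile is the elementwise minimum", {
  rng <- range_from(c(0.1, 0.1), c(s1 = 0.5, s2 = 0.5), c(1, 1))
  expect_equal(common_with_control(c(s1 = 0.9, s2 = 0.7), rng),
               c(s1 = 0.5, s2 = 0.5))
  expect_equal(common_with_control(c(s1 = 0, s2 = 0), rng),
               c(s1 = 0, s2 = 0))
  expect_equal(unname(common_with_control(c(s1 = 0.4, s2 = 0.6), rng)),
               c(0.4, 0.5))
})
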