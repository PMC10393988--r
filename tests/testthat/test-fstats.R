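# Naive per-site brute-force evaluations, kept deliberately separate from
# the implementation.
brute_f3 <- function(f, o, a, b) mean((f[, o] - f[, a]) * (f[, o] - f[, b]),
                                      na.rm = TRUE)
brute_f4 <- function(f, a, b, c, d) mean((f[, a] - f[, b]) * (f[, c] - f[, d]),
                                         na.rm = TRUE)
brute_d <- function(f, w, x, y, z) {
  num <- (f[, w] - f[, x]) * (f[, y] - f[, z])
  den <- (f[, w] + f[, x] - 2 * f[, w] * f[, x]) *
    (f[, y] + f[, z] - 2 * f[, y] * f[, z])
  sum(num) / sum(den)
}

rand_fmat <- function(n = 60, k = 5, seed = 1) {
  set.seed(seed)
  matrix(runif(n * k), n, k, dimnames = list(NULL, LETTERS[1:k]))
}

test_that("f3, f4 and D equal the brute-force per-site evaluation", {
  for (seed in 1:3) {
    f <- rand_fmat(seed = seed)
    blocks <- rep(1:6, length.out = nrow(f))
    expect_equal(fstat_f3(f, "A", "B", "C", blocks)$est,
                 brute_f3(f, "A", "B", "C"), tolerance = 1e-12)
    expect_equal(fstat_f4(f, "A", "B", "C", "D", blocks)$est,
                 brute_f4(f, "A", "B", "C", "D"), tolerance = 1e-12)
    expect_equal(fstat_d(f, "A", "B", "C", "D", blocks)$est,
                 brute_d(f, "A", "B", "C", "D"), tolerance = 1e-12)
  }
})

test_that("the worked two-site f3 example evaluates exactly", {
  f <- cbind(O = c(0, 0), A = c(1, 0.5), B = c(1, 0.5))
  expect_equal(fstat_f3(f, "O", "A", "B", c(1L, 2L))$est, 0.625)
})

test_that("f-statistic symmetries hold exactly", {
  f <- rand_fmat(seed = 9)
  blocks <- rep(1:5, length.out = nrow(f))
  expect_identical(fstat_f3(f, "A", "B", "C", blocks)$est,
                   fstat_f3(f, "A", "C", "B", blocks)$est)
  expect_equal(fstat_f4(f, "A", "B", "C", "D", blocks)$est,
               -fstat_f4(f, "A", "B", "D", "C", blocks)$est, tolerance = 1e-15)
  expect_equal(fstat_d(f, "A", "B", "C", "D", blocks)$est,
               -fstat_d(f, "A", "B", "D", "C", blocks)$est, tolerance = 1e-15)
  # identical final pair: exact zero, and f3 of identical columns vs apex 0
  f2 <- cbind(f, C2 = f[, "C"])
  expect_equal(fstat_d(f2, "A", "B", "C", "C2", blocks)$est, 0)
  same <- cbind(O = f[, "A"], A = f[, "A"], B = f[, "A"])
  expect_equal(fstat_f3(same, "O", "A", "B", blocks)$est, 0)
})

test_that("zero D denominator is rejected with a named cause", {
  f <- cbind(W = c(0, 0), X = c(0, 0), Y = c(1, 1), Z = c(0, 1))
  expect_error(fstat_d(f, "W", "X", "Y", "Z", c(1L, 2L)), "denominator")
})

test_that("weighted jackknife reduces to the classical formula on equal blocks", {
  set.seed(3)
  n <- 200; B <- 10
  x <- rnorm(n)
  blocks <- rep(1:B, each = n / B)
  jk <- block_jackknife(x, blocks)
  est <- mean(x)
  loo <- vapply(1:B, function(b) mean(x[blocks != b]), 0)
  classical <- sqrt((B - 1) / B * sum((loo - mean(loo))^2))
  expect_equal(jk$se, classical, tolerance = 1e-12)
  expect_equal(jk$est, est)
  expect_equal(jk$z, est / classical)
})

test_that("block scheme assigns every site to exactly one genomic block", {
  panel <- toy_panel(5000, seed = 4)
  blocks <- block_scheme(panel)
  expect_equal(length(blocks), 5000L)
  expect_false(anyNA(blocks))
  # sites within a block share chromosome and 5 Mb span
  for (b in sample(unique(blocks), 5)) {
    s <- panel$sites[blocks == b, ]
    expect_equal(length(unique(s$chrom)), 1L)
    expect_lte(max(s$pos) - min(s$pos), 5e6)
  }
})

test_that("cohort filters drop singletons, low-genotyping and kin duplicates", {
  # explicit matrix: site 1 is a singleton (variant carried by i1 only);
  # i4 is genotyped at 17/20 = 85% before but 16/19 = 84.2% of the sites
  # that survive the singleton filter
  g <- matrix(1L, 20, 4, dimnames = list(NULL, paste0("i", 1:4)))
  g[1, ] <- c(1L, 0L, 0L, 0L)
  g[2, ] <- c(0L, 1L, 1L, 0L)
  g[c(3, 4, 5), 4] <- NA
  out <- filter_cohort(g)
  expect_false(out$sites[1])                 # singleton dropped
  expect_true(all(out$sites[-1]))
  expect_false("i4" %in% out$individuals)    # 84.2% < 85% genotyped
  expect_true(all(c("i1", "i2", "i3") %in% out$individuals))

  # kin trio with coverages (0.1, 0.5, 0.2): keep the 0.5 member
  g2 <- matrix(rep(c(1L, 0L), 15), 10, 3,
               dimnames = list(NULL, paste0("k", 1:3)))
  cov <- c(k1 = 0.1, k2 = 0.5, k3 = 0.2)
  out2 <- filter_cohort(g2, coverage = cov,
                        kin_groups = list(c("k1", "k2", "k3")))
  expect_equal(out2$individuals, "k2")
  expect_error(filter_cohort(g2, coverage = cov,
                             kin_groups = list(c("k1", "k2", "k3")),
                             min_genotyped = 1.01),
               "all individuals")
})

test_that("within-group diversity excludes close relatives and ranks cohorts", {
  set.seed(6)
  n <- 4000
  p <- runif(n, 0.2, 0.8)
  outg <- runif(n, 0, 1)
  # low-diversity group: individuals drawn around a drifted common frequency
  drift <- function(f, amt) clamp_freq(rbeta(n, f * (1 - amt) / amt,
                                             (1 - f) * (1 - amt) / amt))
  p_bott <- drift(p, 0.15)
  low <- sapply(1:4, function(i) rbinom(n, 1, p_bott))
  high <- sapply(1:4, function(i) rbinom(n, 1, p))
  fmat <- cbind(low, high, O = outg)
  colnames(fmat) <- c(paste0("L", 1:4), paste0("H", 1:4), "O")
  blocks <- rep(1:20, length.out = n)
  d_low <- within_group_diversity(fmat, paste0("L", 1:4), "O", blocks)
  d_high <- within_group_diversity(fmat, paste0("H", 1:4), "O", blocks)
  expect_lt(d_low$summary$overall[["median"]],
            d_high$summary$overall[["median"]])
  # a duplicated individual (identical degree) is excluded by the kin filter
  kin <- data.frame(id1 = "L1", id2 = "L2", degree_final = "first")
  d_f <- within_group_diversity(fmat, paste0("L", 1:4), "O", blocks, kin = kin)
  expect_false(any(d_f$pairs$id1 == "L1" & d_f$pairs$id2 == "L2"))
  expect_equal(nrow(d_f$pairs), nrow(d_low$pairs) - 1L)
  kin_all <- data.frame(id1 = c("L1", "L1", "L1", "L2", "L2", "L3"),
                        id2 = c("L2", "L3", "L4", "L3", "L4", "L4"),
                        degree_final = "second")
  expect_error(within_group_diversity(fmat, paste0("L", 1:4), "O", blocks,
                                      kin = kin_all), "eligible")
})

test_that("patrilocality D test refuses leakage of the focal individual", {
  fmat <- cbind(O = runif(100), a = runif(100), b = runif(100),
                c = runif(100))
  blocks <- rep(1:4, 25)
  sexes <- c(a = "M", b = "F", c = "M")
  # site of one individual: no others left after removing the focal
  r <- patrilocality_dtest(fmat, c("a", "b"), c("c"), "O", blocks, sexes)
  expect_true(all(c("a", "b") %in% r$per_individual$id))
  # one-sex site: rank test NA, medians for available class only
  r2 <- patrilocality_dtest(fmat, c("a", "c"), c("b"), "O", blocks,
                            sexes)
  expect_true(is.na(r2$rank_test_p))
})
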