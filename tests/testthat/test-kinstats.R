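test_that("P0 mismatch rate handles identical, complementary and empty input", {
  panel <- toy_panel(1000, seed = 1)
  h <- rbinom(1000, 1, 0.5)
  maf_ok <- pmin(panel$freq[, "POP"], 1 - panel$freq[, "POP"]) >= 0.1

  expect_equal(read_p0(h, h, panel, "POP")$p0, 0)
  expect_equal(read_p0(h, 1L - h, panel, "POP")$p0, 1)
  expect_equal(read_p0(h, h, panel, "POP")$n_overlap, sum(maf_ok))
  none <- rep(NA_integer_, 1000)
  expect_true(is.na(read_p0(h, none, panel, "POP")$p0))
  # MAF filter drops low-frequency sites from the overlap
  expect_lt(read_p0(h, h, panel, "POP", min_maf = 0.4)$n_overlap, sum(maf_ok))
})

test_that("self-comparison of two pseudo-haploid samplings halves P0", {
  # the same individual haploidized twice: E[P0_norm] = 1 - phi with
  # phi = 0.5, i.e. about half the unrelated-pair level
  panel <- toy_panel(30000, seed = 2)
  ped <- pedigree_spec(data.frame(
    id = c("a", "b"), sex = "M", generation = 1, age_class = "adult"))
  dr <- gene_drop(ped, panel, "POP", seed = 3)
  sp1 <- sequencing_spec(mean_depth = 5, seed = 4)
  sp2 <- sequencing_spec(mean_depth = 5, seed = 5)
  h_self1 <- call_pseudohaploid(simulate_reads(dr, sp1, individuals = "a")[["a"]],
                                panel, seed = 6, id = "a")
  h_self2 <- call_pseudohaploid(simulate_reads(dr, sp2, individuals = "a")[["a"]],
                                panel, seed = 7, id = "a")
  h_b <- call_pseudohaploid(simulate_reads(dr, sp1, individuals = "b")[["b"]],
                            panel, seed = 8, id = "b")
  p_self <- read_p0(h_self1, h_self2, panel, "POP")$p0
  p_unrel <- read_p0(h_self1, h_b, panel, "POP")$p0
  expect_lt(abs(p_self / p_unrel - 0.5), 0.05)
})

test_that("READ classification uses the midpoint cutoffs", {
  p0 <- c(0.10, 0.12, 0.125, 0.13, 0.121, 0.124, 0.119, 0.122, 0.126, 0.123,
          0.07, 0.095)
  cls <- classify_read(p0)
  med <- median(p0)
  expect_equal(as.character(cls$degree[p0 / med < 0.625][1]), "identical")
  # direct cutoff algebra on explicit normalized values
  cls2 <- classify_read(c(0.60, 1.0, 0.70, 0.85, 0.95) * 0.2, norm = 0.2)
  expect_equal(as.character(cls2$degree),
               c("identical", "unrelated", "first", "second", "unrelated"))
  expect_equal(cls2$p0_normalized, c(0.60, 1.0, 0.70, 0.85, 0.95))
  # boundaries are left-closed
  cls3 <- classify_read(c(0.625, 0.8125, 0.90625), norm = 1)
  expect_equal(as.character(cls3$degree), c("first", "second", "unrelated"))
})

test_that("small cohorts refuse median normalization with advice", {
  expect_error(classify_read(rep(0.2, 9)), "explicit")
  expect_silent(classify_read(rep(0.2, 9), norm = 0.2))
})

test_that("IBS statistics follow the frozen operative formulas", {
  # identical vectors with H het sites: king_theta = H / (2H) = 0.5
  g <- c(0L, 1L, 2L, 1L, 1L, 0L, 2L)
  r <- ibs_stats(g, g)
  expect_equal(r$king_theta, 0.5)
  expect_equal(r$ibs0, 0L)
  expect_equal(r$r0, 0)
  # hand-built counts
  gi <- c(0L, 2L, 1L, 1L, 0L, 2L)
  gj <- c(2L, 0L, 1L, 0L, 0L, 2L)
  r <- ibs_stats(gi, gj)
  expect_equal(r$ibs0, 2L)       # two opposite homozygote sites
  expect_equal(r$n_both_het, 1L)
  expect_equal(r$king_theta, (1 - 2 * 2) / (2 + 1))
  expect_equal(r$r0, 2 / 1)
  expect_equal(r$r1, 1 / (2 + 1))
  # no double-het sites: R0 undefined
  expect_true(is.na(ibs_stats(c(0L, 2L), c(2L, 0L))$r0))
})

test_that("ML k-coefficients recover identity, PO and unrelated dyads", {
  set.seed(10)
  n <- 30000
  p <- runif(n, 0.1, 0.9)
  perfect_gl <- function(g) {
    m <- matrix(1e-8, n, 3); m[cbind(1:n, g + 1)] <- 1; m / rowSums(m)
  }
  g1 <- rbinom(n, 2, p)
  fit_id <- ml_k_coefficients(perfect_gl(g1), perfect_gl(g1), p)
  expect_gt(fit_id$k[["k2"]], 0.95)
  expect_equal(sum(fit_id$k), 1, tolerance = 1e-6)

  transmitted <- rbinom(n, 1, ifelse(g1 == 1, 0.5, g1 / 2))
  child <- transmitted + rbinom(n, 1, p)
  fit_po <- ml_k_coefficients(perfect_gl(g1), perfect_gl(child), p)
  expect_lt(abs(fit_po$k[["k1"]] - 1), 0.05)
  expect_equal(fit_po$theta, unname(fit_po$k["k1"] / 4 + fit_po$k["k2"] / 2))

  g2 <- rbinom(n, 2, p)
  fit_un <- ml_k_coefficients(perfect_gl(g1), perfect_gl(g2), p)
  expect_lt(abs(fit_un$k[["k0"]] - 1), 0.05)
})

test_that("king theta and ML theta agree on high-depth simulations", {
  panel <- toy_panel(20000, seed = 11)
  ped <- toy_family()
  dr <- gene_drop(ped, panel, "POP", seed = 12)
  pu <- simulate_reads(dr, sequencing_spec(mean_depth = 15, base_error = 0,
                                           seed = 13))
  g <- true_genotypes(dr)
  for (pair in list(c("mo", "son"), c("son", "dau"), c("mo", "fa"))) {
    gl1 <- call_genotype_likelihoods(pu[[pair[1]]], panel)$lik
    gl2 <- call_genotype_likelihoods(pu[[pair[2]]], panel)$lik
    fit <- ml_k_coefficients(gl1, gl2, panel$freq[, "POP"])
    king <- ibs_stats(g[, pair[1]], g[, pair[2]])$king_theta
    expect_lt(abs(fit$theta - king), 0.05)
  }
})

test_that("theta_x matches pedigree X-transmission and applies its gate", {
  panel_x <- snp_panel(synth_panel_sites(6000, class = "X"))
  set.seed(14)
  panel_x$freq <- matrix(runif(6000, 0.1, 0.9), ncol = 1,
                         dimnames = list(NULL, "POP"))
  ped <- pedigree_spec(data.frame(
    id = c("mo", "fa", "s1", "s2", "dau"),
    sex = c("F", "M", "M", "M", "F"),
    generation = c(1, 1, 2, 2, 2), age_class = "adult",
    mother = c(NA, NA, "mo", "mo", "mo"),
    father = c(NA, NA, "fa", "fa", "fa")))
  dr <- gene_drop(ped, panel_x, "POP", seed = 15)
  pu <- simulate_reads(dr, sequencing_spec(mean_depth = 8, base_error = 0.001,
                                           seed = 16), class = "X")
  gl <- lapply(setNames(nm = ped$members$id), function(id) {
    call_genotype_likelihoods(pu[[id]], panel_x, ploidy = 2L)$lik
  })
  hap <- function(id) {
    h <- gl[[id]][, c(1, 3)]
    h / rowSums(h)
  }
  f <- panel_x$freq[, "POP"]
  # father-son: no X sharing
  expect_lt(theta_x(hap("fa"), hap("s1"), f, "M", "M")$theta_x, 0.1)
  # brothers: about 0.5
  expect_lt(abs(theta_x(hap("s1"), hap("s2"), f, "M", "M")$theta_x - 0.5), 0.1)
  # mother-son: about 0.5 (X kinship scale)
  expect_lt(abs(theta_x(hap("s1"), gl[["mo"]], f, "M", "F")$theta_x - 0.5), 0.1)
  # father-daughter: about 0.5
  expect_lt(abs(theta_x(hap("fa"), gl[["dau"]], f, "M", "F")$theta_x - 0.5), 0.1)
  # identical male twice: maximal
  expect_gt(theta_x(hap("s1"), hap("s1"), f, "M", "M")$theta_x, 0.9)
  # gate: 999 overlapping sites withholds the estimate
  short <- theta_x(hap("s1")[1:999, ], hap("s2")[1:999, ], f[1:999], "M", "M")
  expect_true(short$gated)
  expect_true(is.na(short$theta_x))
})

test_that("degree consolidation prefers the likelihood-based call on conflict", {
  r <- consolidate_degree("first", "first")
  expect_equal(r$degree, "first"); expect_false(r$conflict)
  r <- consolidate_degree("second", "first")
  expect_equal(r$degree, "first"); expect_true(r$conflict)
  expect_equal(r$source, "ml")
  r <- consolidate_degree("first", NA)
  expect_equal(r$degree, "first"); expect_equal(r$source, "read")
  r <- consolidate_degree(NA, NA)
  expect_true(is.na(r$degree)); expect_equal(r$source, "none")
})

test_that("P0_normalized increases along the degree ladder across depths", {
  for (depth in c(0.5, 2)) {
    r <- study_kinship_replicate(seed = 400 + depth * 10, n_sites = 30000L,
                                 depth = depth)
    expect_lt(r$p0_norm[["po"]], r$p0_norm[["second"]])
    expect_lt(r$p0_norm[["second"]], r$p0_norm[["unrelated"]])
    expect_lt(r$p0_norm[["sib"]], r$p0_norm[["second"]])
  }
})
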