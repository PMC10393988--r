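test_that("zero drift propagates identical frequencies and null f4", {
  g <- admixture_graph(edges = data.frame(
    parent = c("R", "R", "A", "A"), child = c("A", "B", "C", "D"),
    f = 0))
  p <- simulate_graph_frequencies(g, 500, seed = 3)
  expect_equal(p$freq[, "C"], p$freq[, "R"])
  expect_equal(p$freq[, "B"], p$freq[, "D"])
  expect_equal(expected_f4(g, "A", "B", "C", "D"), 0)
})

test_that("two-leaf f2 matches the Balding-Nichols closed form", {
  f1 <- 0.03; f2v <- 0.05
  g <- admixture_graph(edges = data.frame(parent = "R", child = c("L1", "L2"),
                                          f = c(f1, f2v)))
  n <- 20000
  p <- simulate_graph_frequencies(g, n, seed = 9)
  t <- (p$freq[, "L1"] - p$freq[, "L2"])^2
  est <- mean(t)
  se <- stats::sd(t) / sqrt(n)
  # closed form: (F1 + F2) * E[p(1-p)] at the root spectrum
  expected <- (f1 + f2v) * (0.5 - 0.0675 - 0.25)
  expect_equal(expected_f2(g, "L1", "L2"), expected, tolerance = 1e-12)
  expect_lt(abs(est - expected), 3 * se)
})

test_that("alpha = 1 admixture degenerates to the first source", {
  g <- admixture_graph(
    edges = data.frame(parent = "R", child = c("A", "B"), f = c(0.02, 0.02)),
    admixture = data.frame(source_a = "A", source_b = "B", child = "M",
                           alpha = 1, f = 0))
  p <- simulate_graph_frequencies(g, 300, seed = 5)
  expect_equal(p$freq[, "M"], p$freq[, "A"])
})

test_that("cyclic graphs are rejected naming the cycle", {
  expect_error(
    admixture_graph(edges = data.frame(parent = c("R", "A", "B"),
                                       child = c("A", "B", "A"), f = 0.01)),
    "more than one parent|cycle")
  expect_error(
    admixture_graph(edges = data.frame(parent = c("R", "A", "B", "C"),
                                       child = c("X", "B", "C", "A"),
                                       f = 0.01)),
    "cycle involving")
})

test_that("gene drop respects Mendelian and uniparental transmission", {
  ped <- toy_family()
  panel <- toy_panel(4000, seed = 2)
  # add X and Y sites
  xs <- synth_panel_sites(400, class = "X")
  ys <- synth_panel_sites(100, class = "Y")
  all_sites <- rbind(panel$sites[, names(xs)], xs, ys)
  full <- snp_panel(all_sites)
  set.seed(8)
  full$freq <- matrix(runif(nrow(all_sites), 0.05, 0.95), ncol = 1,
                      dimnames = list(NULL, "POP"))
  dr <- gene_drop(ped, full, "POP", seed = 4)

  g <- true_genotypes(dr, "autosome")
  # parent-offspring: no opposite homozygotes
  expect_equal(sum(abs(g[, "mo"] - g[, "son"]) == 2), 0L)
  expect_equal(sum(abs(g[, "fa"] - g[, "son"]) == 2), 0L)
  # father-son: same Y lineage label; son's mito equals mother's
  expect_equal(dr$labels$y[dr$labels$id == "son"],
               dr$labels$y[dr$labels$id == "fa"])
  expect_equal(dr$labels$mito[dr$labels$id == "son"],
               dr$labels$mito[dr$labels$id == "mo"])
  # Y sites transmitted father to son verbatim
  expect_equal(dr$y$h1[, "son"], dr$y$h1[, "fa"])
  # son hemizygous X from mother only
  expect_true(all(is.na(dr$x$h2[, "son"])))
  expect_true(all(dr$x$l1[, "son"] %in% c(dr$x$l1[, "mo"], dr$x$l2[, "mo"])))
  # daughter carries father's X
  expect_equal(dr$x$h2[, "dau"], dr$x$h1[, "fa"])
})

test_that("full siblings realize k2 near the Mendelian quarter", {
  ped <- toy_family()
  panel <- toy_panel(50000, seed = 21)
  dr <- gene_drop(ped, panel, "POP", seed = 22)
  k <- realized_k(dr, "son", "dau")
  expect_lt(abs(k[["k2"]] - 0.25), 0.05)
  expect_lt(abs(k[["k1"]] - 0.5), 0.05)
})

test_that("founder genotypes converge to the input frequencies", {
  n_f <- 500
  members <- data.frame(id = paste0("f", 1:n_f),
                        sex = rep(c("M", "F"), length.out = n_f),
                        generation = 1, age_class = "adult")
  ped <- pedigree_spec(members)
  panel <- toy_panel(200, seed = 31)
  dr <- gene_drop(ped, panel, "POP", seed = 32)
  g <- true_genotypes(dr)
  obs <- rowMeans(g) / 2
  f <- panel$freq[, "POP"]
  se <- sqrt(f * (1 - f) / (2 * n_f))
  expect_gt(mean(abs(obs - f) <= 3 * se), 0.98)
})

test_that("missing parent records are rejected", {
  expect_error(pedigree_spec(data.frame(
    id = "kid", sex = "M", generation = 2, age_class = "adult",
    mother = "ghost", father = "ghost2")), "missing parent")
})

test_that("read simulation honours depth, noise-free limit and damage", {
  ped <- toy_family()
  panel <- toy_panel(2000, seed = 41)
  dr <- gene_drop(ped, panel, "POP", seed = 42)

  # near-zero depth: almost all sites empty
  sp0 <- sequencing_spec(mean_depth = 1e-4, base_error = 0, seed = 1)
  pu0 <- simulate_reads(dr, sp0, individuals = "mo")
  expect_gte(1 - nrow(pu0[["mo"]]) / 2000, 0.999)

  # noiseless high depth: consensus equals truth everywhere covered
  sp30 <- sequencing_spec(mean_depth = 30, base_error = 0, seed = 2)
  pu30 <- simulate_reads(dr, sp30, individuals = "mo")
  cl <- call_genotype_likelihoods(pu30[["mo"]], panel)
  g <- true_genotypes(dr)[, "mo"]
  cov <- !is.na(cl$best)
  expect_true(all(cl$best[cov] == g[cov]))

  # a CC individual at a C/T site shows ~30% T reads at damaged distances
  one <- one_site_panel("C", "T")
  one$freq <- matrix(0.5, 1, 1, dimnames = list(NULL, "POP"))
  hom <- list(panel = one,
              auto = list(h1 = matrix(0L, 1, 1, dimnames = list(NULL, "z")),
                          h2 = matrix(0L, 1, 1, dimnames = list(NULL, "z")),
                          sites = 1L))
  spd <- sequencing_spec(mean_depth = 3000, base_error = 0,
                         damage = flat_damage(0.3, span = 15L), seed = 3)
  pud <- simulate_reads(hom, spd, individuals = "z")
  frac_t <- mean(pud[["z"]]$base == "T")
  n <- nrow(pud[["z"]])
  expect_lt(abs(frac_t - 0.3), 3 * sqrt(0.3 * 0.7 / n))
})

test_that("identical seeds reproduce identical outputs", {
  g <- calibration_graph()
  p1 <- simulate_graph_frequencies(g, 200, seed = 77)
  p2 <- simulate_graph_frequencies(g, 200, seed = 77)
  expect_identical(p1$freq, p2$freq)

  ped <- toy_family()
  panel <- toy_panel(500, seed = 5)
  d1 <- gene_drop(ped, panel, "POP", seed = 6)
  d2 <- gene_drop(ped, panel, "POP", seed = 6)
  expect_identical(d1$auto, d2$auto)
  sp <- sequencing_spec(mean_depth = 2, seed = 7)
  expect_identical(simulate_reads(d1, sp, individuals = "son"),
                   simulate_reads(d2, sp, individuals = "son"))
})

test_that("null graphs produce calibrated f4 Z scores", {
  # no shared drift between the pairs: f4(A,B;C,D) is null
  g <- admixture_graph(edges = data.frame(
    parent = c("R", "R", "R", "R"), child = c("A", "B", "C", "D"),
    f = 0.02))
  zs <- vapply(1:40, function(r) {
    p <- simulate_graph_frequencies(g, 4000, seed = 100 + r)
    fstat_f4(p$freq, "A", "B", "C", "D", block_scheme(p))$z
  }, 0)
  expect_lte(mean(abs(zs) > 1.96), 0.05 + 3 * sqrt(0.05 * 0.95 / 40))
})
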