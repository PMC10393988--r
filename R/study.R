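#' Reference study simulations
#'
#' The functions in this file define the package's reference experiments:
#' fixed synthetic study conditions under which every stage of the pipeline
#' is exercised end to end against known truth.  The analysis scripts, the
#' test suite and the acceptance script all run these same experiments.
#'
#' @name paleokin-studies
NULL

#' Six-population admixture graph used for f-statistic calibration
#'
#' A fixed topology with one admixed leaf: outgroup O, leaves A-D on a
#' nested backbone, and E an alpha = 0.4 mixture of the A and C lineages.
#'
#' @return an [admixture_graph()].
#' @export
calibration_graph <- function() {
  admixture_graph(
    edges = data.frame(
      parent = c("R", "R", "X1", "X1", "X2", "X2", "X3", "X3"),
      child  = c("O", "X1", "A", "X2", "B", "X3", "C", "D"),
      f      = c(0.08, 0.02, 0.03, 0.01, 0.02, 0.015, 0.02, 0.025)),
    admixture = data.frame(source_a = "A", source_b = "C", child = "E",
                           alpha = 0.4, f = 0.01))
}

#' f4 calibration against the closed-form graph expectation
#'
#' Simulates the calibration graph, estimates every f4 over the six leaf
#' populations with block-jackknife standard errors, and compares each to
#' its exact path-overlap expectation.
#'
#' @param seed RNG seed.
#' @param n_sites sites simulated (default 50000).
#' @return data.frame per statistic: populations, estimate, se, expected,
#'   and `within3` (|est - expected| <= 3 se).
#' @export
study_f4_calibration <- function(seed, n_sites = 50000L) {
  g <- calibration_graph()
  panel <- simulate_graph_frequencies(g, n_sites, seed = seed)
  blocks <- block_scheme(panel)
  leaves <- c("O", "A", "B", "C", "D", "E")
  rows <- list()
  for (quad in utils::combn(leaves, 4L, simplify = FALSE)) {
    # three distinct pairings per quadruple
    arr <- list(quad, quad[c(1, 3, 2, 4)], quad[c(1, 4, 2, 3)])
    for (q in arr) {
      r <- fstat_f4(panel$freq, q[1], q[2], q[3], q[4], blocks)
      exp_val <- expected_f4(g, q[1], q[2], q[3], q[4])
      rows[[length(rows) + 1L]] <- data.frame(
        a = q[1], b = q[2], c = q[3], d = q[4], est = r$est, se = r$se,
        expected = exp_val, within3 = abs(r$est - exp_val) <= 3 * r$se,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Admixture graph with a two-way mixed target for weight recovery
#'
#' Sources S1 and S2 sit on two sister lineages, each with a nearby right
#' population (R1, R2) plus distal rights (r0, R3, R4); the target T is an
#' `alpha` : 1-alpha mixture of S1 and S2 with a little private drift.
#'
#' @param alpha mixture proportion of S1 (default 0.3).
#' @return an [admixture_graph()].
#' @export
qpadm_graph <- function(alpha = 0.3) {
  admixture_graph(
    edges = data.frame(
      parent = c("R", "R", "R", "W", "W", "W", "W1", "W1", "W2", "W2"),
      child  = c("r0", "R4", "W", "W1", "W2", "R3", "S1", "R1", "S2", "R2"),
      f      = c(0.05, 0.07, 0.01, 0.02, 0.02, 0.05, 0.02, 0.03, 0.02, 0.03)),
    admixture = data.frame(source_a = "S1", source_b = "S2", child = "T",
                           alpha = alpha, f = 0.005))
}

#' Two-way admixture-weight recovery study
#'
#' For each replicate, simulates the [qpadm_graph()] and fits (i) the true
#' two-way model through the nested rule and (ii) a deliberately wrong
#' single-source model, recording the estimated alpha, the plausibility
#' verdicts and p-values.
#'
#' @param seed base RNG seed; replicate r uses `seed + r`.
#' @param reps replicates (default 20).
#' @param n_sites sites per replicate (default 50000).
#' @param alpha true mixture proportion (default 0.3).
#' @return data.frame per replicate: `alpha_hat`, `true_plausible`,
#'   `true_p`, `wrong_single_p`, `wrong_rejected`.
#' @export
study_qpadm_recovery <- function(seed, reps = 20L, n_sites = 50000L,
                                 alpha = 0.3) {
  g <- qpadm_graph(alpha)
  rights <- c("r0", "R1", "R2", "R3", "R4")
  rows <- vector("list", reps)
  for (r in seq_len(reps)) {
    panel <- simulate_graph_frequencies(g, n_sites, seed = seed + r)
    blocks <- block_scheme(panel)
    nr <- nested_rule(panel$freq, "T", c("S1", "S2"), rights, blocks)
    wrong <- fit_weights(panel$freq, "T", "S1", rights, blocks)
    rows[[r]] <- data.frame(
      alpha_hat = unname(nr$full$weights["S1"]),
      true_p = nr$full$p_value,
      true_plausible = nr$plausible,
      wrong_single_p = wrong$p_value,
      wrong_rejected = wrong$p_value < 0.05)
  }
  do.call(rbind, rows)
}

#' Family pedigree used by the kinship recovery study
#'
#' A three-generation family (parents, two full siblings, one grandchild)
#' plus unrelated adults from the same population, giving one dyad of each
#' class: parent-offspring (pa-s1), full siblings (s1-s2), second degree
#' (ma-gc, grandmother-grandchild) and unrelated (u1-u2).
#'
#' @param n_unrelated unrelated adults included (default 6).
#' @return a [pedigree_spec()].
#' @export
kinship_study_pedigree <- function(n_unrelated = 6L) {
  u <- paste0("u", seq_len(n_unrelated))
  pedigree_spec(data.frame(
    id = c(u, "pa", "ma", "sp1", "s1", "s2", "gc"),
    sex = c(rep(c("M", "F"), length.out = n_unrelated),
            "M", "F", "F", "M", "F", "M"),
    generation = c(rep(1L, n_unrelated), 1L, 1L, 2L, 2L, 2L, 3L),
    age_class = "adult",
    mother = c(rep(NA, n_unrelated), NA, NA, NA, "ma", "ma", "sp1"),
    father = c(rep(NA, n_unrelated), NA, NA, NA, "pa", "pa", "s1"),
    stringsAsFactors = FALSE))
}

#' Kinship recovery under low-coverage pseudo-haploid conditions
#'
#' One replicate: drift a study population from a reference population,
#' gene-drop the [kinship_study_pedigree()], sequence everyone at the given
#' depth with terminal deamination, pseudo-haploidize and call genotype
#' likelihoods (damage-aware), then estimate READ-style degrees for all
#' pairs (cohort-median normalization) and ML k-coefficients for the four
#' benchmark dyads.
#'
#' @param seed RNG seed.
#' @param n_sites autosomal candidate sites (default 160000, chosen so a
#'   per-site depth of 1 leaves over 50000 overlapping pseudo-haploid
#'   sites per pair after the MAF filter).
#' @param depth mean reads per site for the pseudo-haploid stage (default
#'   1; the likelihood-based k estimate uses `depth_ml`).
#' @param depth_ml mean depth for the genotype-likelihood dyad (default 4;
#'   k0/k1/k2 are only weakly identified below ~2x, where only theta is
#'   estimable).
#' @param damage terminal deamination rate (default 0.2 over 3 positions).
#' @return list with `dyads` (benchmark dyad classifications), `k1_po`
#'   (ML k1 of the parent-offspring dyad), `p0_norm` (named normalized P0
#'   of the benchmark dyads), `n_overlap` per dyad.
#' @export
study_kinship_replicate <- function(seed, n_sites = 160000L, depth = 1,
                                    depth_ml = 4, damage = 0.2) {
  ped <- kinship_study_pedigree()
  panel <- snp_panel(synth_panel_sites(n_sites))
  set.seed(seed)
  panel$freq <- matrix(stats::runif(n_sites, 0.05, 0.95), ncol = 1,
                       dimnames = list(NULL, "POP"))
  drop <- gene_drop(ped, panel, "POP", seed = seed)
  prof <- flat_damage(damage, span = 3L)
  sspec <- sequencing_spec(mean_depth = depth, base_error = 0.001,
                           damage = prof, seed = seed + 1L)
  pu <- simulate_reads(drop, sspec)
  ids <- ped$members$id
  hap <- matrix(NA_integer_, n_sites, length(ids), dimnames = list(NULL, ids))
  for (id in ids) hap[, id] <- call_pseudohaploid(pu[[id]], panel,
                                                  seed = seed, id = id)
  dyads <- list(po = c("pa", "s1"), sib = c("s1", "s2"),
                second = c("ma", "gc"), unrelated = c("u1", "u2"))
  # READ: cohort-median normalization over all pairs
  pairs <- utils::combn(ids, 2L)
  p0 <- vapply(seq_len(ncol(pairs)), function(k) {
    read_p0(hap[, pairs[1, k]], hap[, pairs[2, k]], panel, "POP")$p0
  }, 0)
  cls <- classify_read(p0)
  key <- paste(pairs[1, ], pairs[2, ])
  pick <- function(d) which(key == paste(d[1], d[2]) | key == paste(d[2], d[1]))
  degree <- vapply(dyads, function(d) as.character(cls$degree[pick(d)]), "")
  p0n <- vapply(dyads, function(d) cls$p0_normalized[pick(d)], 0)
  n_ov <- vapply(dyads, function(d) {
    read_p0(hap[, d[1]], hap[, d[2]], panel, "POP")$n_overlap
  }, 0L)
  # ML k for the parent-offspring dyad on a thinned per-pair panel, at the
  # higher depth the likelihood model needs to separate k1 from k0/k2
  sspec_ml <- sequencing_spec(mean_depth = depth_ml, base_error = 0.001,
                              damage = prof, seed = seed + 2L)
  pu_ml <- simulate_reads(drop, sspec_ml, individuals = c("pa", "s1"))
  gl_pa <- call_genotype_likelihoods(pu_ml[["pa"]], panel, damage = prof)$lik
  gl_s1 <- call_genotype_likelihoods(pu_ml[["s1"]], panel, damage = prof)$lik
  both <- which(!is.na(gl_pa[, 1]) & !is.na(gl_s1[, 1]))
  sub <- panel_subset(panel, both)
  kept <- both[match(thin_by_distance(sub, 2500)$sites$id, sub$sites$id)]
  fit <- ml_k_coefficients(gl_pa[kept, ], gl_s1[kept, ], panel$freq[kept, "POP"])
  list(dyads = degree, k1_po = unname(fit$k["k1"]), p0_norm = p0n,
       n_overlap = n_ov)
}

#' Y-haplogroup assignment recovery study
#'
#' On a random 50-node tree, simulates damaged, partially missing call
#' sets from random generating nodes, applies the recoding rules and the
#' assignment procedure, and reports recovery.
#'
#' @param seed RNG seed (tree and replicates derive from it).
#' @param reps replicates (default 100).
#' @param n_nodes tree size (default 50).
#' @param missing_rate fraction of markers uncalled (default 0.2).
#' @return logical vector: per replicate, assigned == generating node.
#' @export
study_y_recovery <- function(seed, reps = 100L, n_nodes = 50L,
                             missing_rate = 0.2) {
  tree <- random_haplogroup_tree(n_nodes, markers_per_branch = 3L,
                                 seed = seed)
  set.seed(seed + 1L)
  truth <- sample(tree$nodes$haplogroup[-1], reps, replace = TRUE)
  vapply(seq_len(reps), function(r) {
    calls <- simulate_y_calls(tree, truth[r], missing_rate = missing_rate,
                              damage_rate = 0.3, lowq_rate = 0.3,
                              seed = seed + 1L + r)
    usable <- recode_y_calls(calls, tree)
    assign_haplogroup(usable$calls, tree)$haplogroup == truth[r]
  }, TRUE)
}

#' Sex-biased admixture and the autosome/X f3 contrast
#'
#' Simulates a target population that is an `alpha_auto` mixture of a
#' hunter-gatherer-like source on the autosomes but only `alpha_x` on the
#' X chromosome (male-driven gene flow transmits autosomes but few X
#' copies), computes the autosome-versus-X f3 contrast over a panel of
#' partner populations, and reports the residual of the HG-like partner.
#'
#' @param seed RNG seed.
#' @param reps replicates (default 20).
#' @param alpha_auto,alpha_x autosomal and X admixture proportions from
#'   the HG source (defaults 0.35 and 0.1; equal values give the unbiased
#'   control).
#' @param n_auto,n_x panel sizes (defaults 30000 and 10000).
#' @return numeric vector: per replicate, the standardized residual of the
#'   HG partner (positive = autosomal affinity elevated relative to X).
#' @export
study_sexbias <- function(seed, reps = 20L, alpha_auto = 0.35,
                          alpha_x = 0.1, n_auto = 30000L, n_x = 10000L) {
  build <- function(alpha) {
    admixture_graph(
      edges = data.frame(
        parent = c("R", "R", "R", "B", "B", "B", "F1", "F1"),
        child  = c("O", "HG", "B", "F1", "N1", "N2", "FARM", "N3"),
        f      = c(0.10, 0.06, 0.01, 0.01, 0.05, 0.03, 0.03, 0.04)),
      admixture = data.frame(source_a = "HG", source_b = "FARM",
                             child = "T", alpha = alpha, f = 0.005))
  }
  g_auto <- build(alpha_auto)
  g_x <- build(alpha_x)
  partners <- c("HG", "FARM", "N1", "N2", "N3")
  vapply(seq_len(reps), function(r) {
    pa <- simulate_graph_frequencies(g_auto, n_auto, seed = seed + 2L * r)
    px_panel <- snp_panel(synth_panel_sites(n_x, class = "X",
                                            chrom_length = 1.5e8))
    px <- simulate_graph_frequencies(g_x, n_x, seed = seed + 2L * r + 1L,
                                     panel = px_panel)
    ct <- x_autosome_contrast(pa$freq, px$freq, "T", partners, "O",
                              block_scheme(pa), block_scheme(px))
    ct$residual[ct$partner == "HG"]
  }, 0)
}

#' Patrilocal-site pedigree: resident patriline with in-marrying females
#'
#' Three generations of a male lineage (all sharing one Y label) with
#' founder wives, plus two in-married females without sampled offspring.
#'
#' @return a [pedigree_spec()].
#' @export
patrilocal_site_pedigree <- function() {
  pedigree_spec(data.frame(
    id = c("P0", "Wa", "Wb", "Wc", "Wd", "We",
           "S1", "S2", "T1", "T2", "T3"),
    sex = c("M", "F", "F", "F", "F", "F", "M", "M", "M", "M", "M"),
    generation = c(1, 1, 2, 2, 3, 3, 2, 2, 3, 3, 3),
    age_class = "adult",
    mother = c(NA, NA, NA, NA, NA, NA, "Wa", "Wa", "Wb", "Wb", "Wc"),
    father = c(NA, NA, NA, NA, NA, NA, "P0", "P0", "S1", "S1", "S2"),
    stringsAsFactors = FALSE))
}

#' Patrilocality study: site-affinity D by sex and haplogroup diversity
#'
#' One replicate: drift a culture population, gene-drop the patrilocal
#' site pedigree alongside unrelated culture individuals (the cohort),
#' compute the per-individual site-affinity D (relatives excluded from the
#' site term), and summarize Y versus mitochondrial haplotype diversity
#' from the reconstructed pedigree.
#'
#' @param seed RNG seed.
#' @param n_sites sites (default 20000).
#' @param n_cohort unrelated culture individuals (default 10).
#' @return list with `d_male_median`, `d_female_median`, `rank_p`,
#'   `h_y`, `h_mt`, `male_kin_frac`, `female_kin_frac`.
#' @export
study_patrilocality_replicate <- function(seed, n_sites = 20000L,
                                          n_cohort = 10L) {
  site_ped <- patrilocal_site_pedigree()
  coh <- paste0("c", seq_len(n_cohort))
  members <- rbind(site_ped$members,
                   data.frame(id = coh, sex = rep(c("M", "F"),
                                                  length.out = n_cohort),
                              generation = 1L, age_class = "adult",
                              mother = NA, father = NA,
                              mito = NA, y = NA))
  ped <- pedigree_spec(members)
  g <- admixture_graph(edges = data.frame(parent = c("R", "R"),
                                          child = c("O", "C"),
                                          f = c(0.1, 0.05)))
  panel <- simulate_graph_frequencies(g, n_sites, seed = seed)
  drop <- gene_drop(ped, panel, "C", seed = seed + 1L)
  geno <- true_genotypes(drop)
  fmat <- cbind(geno / 2, O = panel$freq[, "O"])
  blocks <- block_scheme(panel)
  site_ids <- site_ped$members$id
  sexes <- stats::setNames(ped$members$sex, ped$members$id)
  truth <- pedigree_truth_evidence(ped)
  dt <- patrilocality_dtest(fmat, site_ids, coh, "O", blocks, sexes,
                            kin = truth$pairs)
  # social-structure summary from the reconstructed site pedigree
  site_truth <- pedigree_truth_evidence(site_ped)
  graph <- build_pedigree(site_truth$pairs, site_truth$meta)
  ss <- summarize_social_structure(graph)
  kc <- ss$kin_counts
  list(d_male_median = unname(dt$by_sex["M"]),
       d_female_median = unname(dt$by_sex["F"]),
       rank_p = dt$rank_test_p,
       h_y = ss$h_y_males, h_mt = ss$h_mito_males,
       male_kin_frac = kc[["adult_males_with_kin"]] / kc[["adult_males_total"]],
       female_kin_frac = kc[["adult_females_with_kin"]] /
         kc[["adult_females_total"]])
}

#' Four-generation pedigree fixture for exact reconstruction
#'
#' Twelve members over four generations covering every rule of the engine:
#' a founder couple, two brothers with in-married wives, grandchildren,
#' and great-grandchildren, yielding 16 first-degree and 15 second-degree
#' relationships.
#'
#' @return a [pedigree_spec()].
#' @export
four_generation_pedigree <- function() {
  pedigree_spec(data.frame(
    id = c("F0a", "F0b", "B1", "B2", "W1", "W2", "C1", "C2", "D1", "W3",
           "E1", "E2"),
    sex = c("M", "F", "M", "M", "F", "F", "M", "F", "M", "F", "M", "F"),
    generation = c(1, 1, 2, 2, 2, 2, 3, 3, 3, 3, 4, 4),
    age_class = c("adult", "adult", "adult", "adult", "adult", "adult",
                  "adult", "adult", "juvenile", "adult", "juvenile",
                  "juvenile"),
    mother = c(NA, NA, "F0b", "F0b", NA, NA, "W1", "W1", "W2", NA,
               "W3", "W3"),
    father = c(NA, NA, "F0a", "F0a", NA, NA, "B1", "B1", "B2", NA,
               "C1", "C1"),
    stringsAsFactors = FALSE))
}

#' Exact pedigree reconstruction check
#'
#' Builds the complete error-free evidence for [four_generation_pedigree()],
#' runs the rule engine, and compares every reconstructed edge to the
#' truth: parent-offspring orientation, sibling typing, and the
#' grandparental/avuncular subtype of every second-degree edge.
#'
#' @return list with `exact` (logical), `graph`, and `mismatches`
#'   (character description of any deviation).
#' @export
study_pedigree_exact <- function() {
  ped <- four_generation_pedigree()
  truth <- pedigree_truth_evidence(ped)
  graph <- build_pedigree(truth$pairs, truth$meta)
  m <- ped$members
  mism <- character(0)
  e <- graph$edges
  key <- paste(pmin(e$id1, e$id2), pmax(e$id1, e$id2))
  find_edge <- function(a, b) which(key == paste(min(a, b), max(a, b)))
  # every true parent link present, typed po, correctly oriented
  for (i in seq_len(nrow(m))) {
    for (par in c(m$mother[i], m$father[i])) {
      if (is.na(par)) next
      idx <- find_edge(par, m$id[i])
      if (length(idx) != 1L || e$type[idx] != "po" ||
            is.na(e$parent[idx]) || e$parent[idx] != par) {
        mism <- c(mism, paste0("parent link ", par, "->", m$id[i]))
      }
    }
  }
  # sibling pairs
  sib_expected <- list(c("B1", "B2"), c("C1", "C2"), c("E1", "E2"))
  for (sp in sib_expected) {
    idx <- find_edge(sp[1], sp[2])
    if (length(idx) != 1L || e$type[idx] != "sibling") {
      mism <- c(mism, paste0("sibling ", sp[1], "-", sp[2]))
    }
  }
  # second-degree subtypes
  expect2 <- rbind(
    data.frame(a = c("F0a", "F0a", "F0a", "F0b", "F0b", "F0b",
                     "B1", "B1", "W1", "W1"),
               b = c("C1", "C2", "D1", "C1", "C2", "D1",
                     "E1", "E2", "E1", "E2"),
               subtype = "grandparental"),
    data.frame(a = c("B2", "B2", "B1", "C2", "C2"),
               b = c("C1", "C2", "D1", "E1", "E2"),
               subtype = "avuncular"))
  for (r in seq_len(nrow(expect2))) {
    idx <- find_edge(expect2$a[r], expect2$b[r])
    if (length(idx) != 1L || e$type[idx] != "second" ||
          is.na(e$subtype[idx]) || e$subtype[idx] != expect2$subtype[r]) {
      mism <- c(mism, paste0("second-degree ", expect2$a[r], "-",
                             expect2$b[r], " != ", expect2$subtype[r]))
    }
  }
  n_expected <- 2 * sum(!is.na(m$mother)) + length(sib_expected) +
    nrow(expect2)
  if (nrow(e) != n_expected) {
    mism <- c(mism, paste0("edge count ", nrow(e), " != ", n_expected))
  }
  list(exact = length(mism) == 0L, graph = graph, mismatches = mism)
}
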