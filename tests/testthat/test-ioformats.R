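test_that("panel invariants are enforced and mutation classes derived", {
  sites <- data.frame(id = c("a", "b"), chrom = "chr1", class = "autosome",
                      pos = c(10L, 20L), a1 = c("A", "C"), a2 = c("G", "A"))
  p <- snp_panel(sites)
  expect_equal(p$sites$mut, c("transition", "transversion"))

  bad <- sites; bad$pos <- c(20L, 10L)
  expect_error(snp_panel(bad), "increasing")
  bad <- sites; bad$a2 <- bad$a1
  expect_error(snp_panel(bad), "differ")
  bad <- sites; bad$id <- c("a", "a")
  expect_error(snp_panel(bad), "duplicate")
})

test_that("distance thinning follows the greedy left-to-right scan", {
  sites <- data.frame(id = paste0("s", 1:4), chrom = "chr1",
                      class = "autosome", pos = c(100L, 2000L, 2700L, 5300L),
                      a1 = "A", a2 = "C")
  p <- snp_panel(sites)
  kept <- thin_by_distance(p, 2500)$sites$pos
  expect_equal(kept, c(100L, 2700L, 5300L))
  expect_equal(thin_by_distance(p, 0)$sites$pos, p$sites$pos)
  single <- snp_panel(sites[1, ])
  expect_equal(nrow(thin_by_distance(single, 1e6)$sites), 1L)
})

test_that("transversion panel applies the outgroup MAF ascertainment", {
  set.seed(1)
  sites <- synth_panel_sites(500)
  freq <- matrix(runif(500, 0, 0.5), ncol = 1, dimnames = list(NULL, "YRI"))
  p <- snp_panel(sites, freq = freq)
  tv <- transversion_panel(p, "YRI", min_maf = 0.1)
  expect_true(all(tv$sites$mut == "transversion"))
  expect_true(all(pmin(tv$freq[, "YRI"], 1 - tv$freq[, "YRI"]) >= 0.1))
  expect_error(transversion_panel(p, "CEU"), "CEU")
})

test_that("EIGENSTRAT round-trips and rejects malformed input", {
  set.seed(7)
  n <- 30; m <- 4
  panel <- snp_panel(synth_panel_sites(n))
  dip <- matrix(sample(c(0:2, NA), n * m, replace = TRUE), n, m)
  ind <- data.frame(id = paste0("i", 1:m), sex = "U", group = "G")
  store <- geno_store(panel, ind, diploid = dip)
  pre <- file.path(tempdir(), "es_test")
  write_eigenstrat(store, pre)
  back <- read_eigenstrat(pre)
  expect_equal(unname(back$diploid), unname(dip))
  expect_equal(back$panel$sites$pos, panel$sites$pos)
  expect_equal(back$panel$sites$a1, panel$sites$a1)
  expect_equal(back$ind$id, ind$id)

  # '9' means missing
  expect_true(anyNA(back$diploid))

  # ragged geno line is rejected with its line number
  lines <- readLines(paste0(pre, ".geno"))
  lines[3] <- substr(lines[3], 1, 2)
  writeLines(lines, paste0(pre, ".geno"))
  expect_error(read_eigenstrat(pre), "line 3")

  # decreasing snp positions are rejected naming the line
  write_eigenstrat(store, pre)
  snp <- read.table(paste0(pre, ".snp"))
  snp[2, 4] <- snp[1, 4] - 1
  write.table(snp, paste0(pre, ".snp"), quote = FALSE, sep = "\t",
              row.names = FALSE, col.names = FALSE)
  expect_error(read_eigenstrat(pre), "line 2|not strictly increasing")
})

test_that("VCF-GL writes and reads PL, GQ, GT and AF tags", {
  set.seed(11)
  n <- 40; m <- 3
  panel <- snp_panel(synth_panel_sites(n),
                     freq = matrix(runif(n), ncol = 1,
                                   dimnames = list(NULL, "WEU")))
  dip <- matrix(sample(c(0:2, NA), n * m, replace = TRUE), n, m)
  gl <- array(NA_real_, c(n, m, 3)); gq <- matrix(NA_real_, n, m)
  for (j in 1:m) {
    cov <- !is.na(dip[, j]); k <- sum(cov)
    raw <- matrix(runif(3 * k, 0.01, 1), k, 3)
    gl[cov, j, ] <- raw / rowSums(raw)
    gq[cov, j] <- sample(10:90, k, replace = TRUE)
  }
  store <- geno_store(panel, data.frame(id = paste0("i", 1:m)),
                      diploid = dip, gl = gl, gq = gq)
  path <- file.path(tempdir(), "t.vcf")
  write_vcf_gl(store, path)
  back <- read_vcf_gl(path)
  expect_equal(unname(back$diploid), unname(dip))
  expect_equal(back$gq, round(gq))                    # integer precision
  expect_lt(max(abs(back$gl - gl), na.rm = TRUE), 0.06)  # PL rounding
  expect_lt(max(abs(back$panel$freq[, "WEU"] - panel$freq[, "WEU"])), 1e-5)
  # likelihood triples re-normalize
  tot <- back$gl[, , 1] + back$gl[, , 2] + back$gl[, , 3]
  expect_lt(max(abs(tot - 1), na.rm = TRUE), 1e-6)
})

test_that("phred PL definition maps to normalized linear likelihoods", {
  # PL = 0,30,200 -> linear proportional to (1, 1e-3, 1e-20)
  path <- file.path(tempdir(), "pl.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
    "##FORMAT=<ID=PL,Number=G,Type=Integer,Description=\"p\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1",
    "chr1\t100\tv1\tA\tC\t.\tPASS\t.\tGT:PL\t0/0:0,30,200"), path)
  st <- read_vcf_gl(path)
  lin <- c(1, 1e-3, 1e-20)
  expect_equal(as.numeric(st$gl[1, 1, ]), lin / sum(lin), tolerance = 1e-10)
})

test_that("multiallelic records are skipped with a reported count", {
  path <- file.path(tempdir(), "multi.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
    "##FORMAT=<ID=PL,Number=G,Type=Integer,Description=\"p\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1",
    "chr1\t100\tv1\tA\tC\t.\tPASS\t.\tGT:PL\t0/0:0,30,200",
    "chr1\t200\tv2\tA\tC,G\t.\tPASS\t.\tGT:PL\t0/0:0,30,200,40,50,60"), path)
  expect_message(st <- read_vcf_gl(path), "1 multiallelic")
  expect_equal(nrow(st$panel$sites), 1L)
  expect_equal(attr(st, "n_multiallelic"), 1L)
})

test_that("a VCF without PL or GL on any record is rejected", {
  path <- file.path(tempdir(), "nopl.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1",
    "chr1\t100\tv1\tA\tC\t.\tPASS\t.\tGT\t0/0"), path)
  expect_error(read_vcf_gl(path), "PL or GL")
})

test_that("round-trip holds for fuzzed random stores", {
  set.seed(99)
  for (rep in 1:3) {
    n <- sample(5:40, 1); m <- sample(1:5, 1)
    panel <- snp_panel(synth_panel_sites(n, n_chrom = 3L))
    dip <- matrix(sample(c(0:2, NA), n * m, replace = TRUE), n, m)
    store <- geno_store(panel, data.frame(id = paste0("x", 1:m)),
                        diploid = dip)
    pre <- file.path(tempdir(), paste0("fz", rep))
    write_eigenstrat(store, pre)
    expect_equal(unname(read_eigenstrat(pre)$diploid), unname(dip))
  }
})
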