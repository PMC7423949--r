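test_that("coalescent simulator matches closed-form E[S]", {
  # n = 2: E[S] = theta
  set.seed(21)
  s2 <- replicate(400, simulate_window_genotypes(3, 2)$S)
  se <- stats::sd(s2) / sqrt(length(s2))
  expect_lt(abs(mean(s2) - 3), 3 * se)

  # genotype matrix is 0/1 with every column segregating
  sim <- simulate_window_genotypes(10, 12, seed = 99)
  gm <- sim$genotypes
  expect_true(all(gm %in% c(0L, 1L)))
  if (ncol(gm) > 0) {
    cs <- colSums(gm)
    expect_true(all(cs >= 1 & cs <= 11))
  }
  expect_error(simulate_window_genotypes(0, 5), "theta")
  expect_error(simulate_window_genotypes(1, 1), "chromosomes")
})

test_that("demographies shift Tajima's D in the expected directions", {
  set.seed(22)
  d_of <- function(demog) {
    mean(replicate(150, {
      s <- simulate_window_genotypes(5, 20, demog)
      tajima_d(s$S, 20, mean_pairwise_diff(s$genotypes))
    }), na.rm = TRUE)
  }
  d_const <- d_of(demography_constant())
  d_exp <- d_of(demography_expansion())
  d_con <- d_of(demography_contraction())
  expect_lt(d_exp, d_const)
  expect_gt(d_con, d_const)
  expect_error(demography_expansion(factor = 0.5), "invalid")
})

test_that("theta is recovered by windowed pi under neutrality", {
  set.seed(23)
  theta <- 20
  wlen <- 1e5
  pis <- replicate(500, {
    s <- simulate_window_genotypes(theta, 50)
    mean_pairwise_diff(s$genotypes)
  })
  expect_lt(abs(stats::median(pis) - theta) / theta, 0.15)
})

test_that("fixtures are byte-identical under the same seed", {
  sc <- sim_scenario(seed = 31, chrom_lengths = c(A1 = 2e5, Y = 2e5),
                     chrom_classes = c(A1 = "AUTOSOME", Y = "Y"),
                     theta_autosome = 20, gap_plan = list(Y = c(20000)))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  f1 <- emit_fixture(sc, d1)
  f2 <- emit_fixture(sc, d2)
  for (k in c("fasta", "gff3", "vcf", "classes", "truth_path")) {
    expect_identical(unname(tools::md5sum(f1[[k]])),
                     unname(tools::md5sum(f2[[k]])))
  }
})

test_that("emitted fixtures have the planned structure", {
  sc <- sim_scenario(seed = 32, chrom_lengths = c(A1 = 2e5, X = 2e5, Y = 2e5),
                     chrom_classes = c(A1 = "AUTOSOME", X = "X", Y = "Y"),
                     theta_autosome = 20, n_diploid_samples = 6, n_male = 3,
                     gap_plan = list(Y = c(30000, 15000)))
  dir <- withr::local_tempdir()
  fx <- emit_fixture(sc, dir)

  fa <- Biostrings::readDNAStringSet(fx$fasta)
  expect_equal(names(fa), c("A1", "X", "Y"))
  expect_equal(unname(Biostrings::width(fa)), rep(2e5, 3))

  # planted gaps recovered exactly by detect_gap_runs
  runs <- detect_gap_runs(fx$fasta)
  truth_gaps <- fx$truth$gaps$Y
  expect_equal(runs$start[runs$chrom == "Y"], sort(truth_gaps$start))
  expect_equal(sum(runs$end - runs$start + 1L), 45000L)

  # Y records: haploid male genotypes only, AN = n_male
  cm <- chromosome_class_map(c("A1", "X", "Y"), c("AUTOSOME", "X", "Y"))
  sites <- read_vcf(fx$vcf, cm)
  ysites <- sites[sites$chrom == "Y", ]
  expect_gt(nrow(ysites), 0)
  expect_true(all(ysites$an == 3L))
  raw <- readLines(fx$vcf)
  yrec <- strsplit(grep("^Y\t", raw, value = TRUE), "\t")
  for (r in yrec) {
    gts <- r[10:12]
    expect_true(all(gts[1:3] %in% c("0", "1", ".")))
    expect_true(all(r[13:15] == "."))
  }

  # autosomes and X: diploid genotypes, AN = 2 * samples
  expect_true(all(sites$an[sites$chrom != "Y"] == 12L))

  # truth covers every emitted window
  expect_equal(length(fx$truth$windows), 3 * 2)

  # INFO AN/AC match the GT-recomputed values
  body <- raw[!startsWith(raw, "#")]
  info_an <- as.integer(sub(".*AN=(\\d+).*", "\\1", body))
  info_ac <- as.integer(sub(".*AC=(\\d+).*", "\\1", body))
  key <- paste0(sub("^(\\S+)\t(\\d+).*", "\\1:\\2", body))
  first <- !duplicated(sites$site_key)
  m <- match(sites$site_key[first], key)
  expect_equal(sites$an[first], info_an[m])
  expect_equal(sites$ac[first], info_ac[m])
})

test_that("hotspot planting multiplies one window's theta and truth flags it", {
  sc <- sim_scenario(seed = 33, chrom_lengths = c(A1 = 5e5),
                     chrom_classes = c(A1 = "AUTOSOME"),
                     theta_autosome = 15, gap_plan = list())
  expect_identical(plant_hotspot(sc, "A1", 2, 1), sc)
  expect_error(plant_hotspot(sc, "A1", 99, 2), "unknown window")
  expect_error(plant_hotspot(sc, "Z", 1, 2), "unknown chromosome")

  sc2 <- plant_hotspot(sc, "A1", 2, 20)
  sc2 <- plant_hotspot(sc2, "A1", 4, 20)
  dir <- withr::local_tempdir()
  fx <- emit_fixture(sc2, dir)
  wins <- fx$truth$windows
  flagged <- vapply(wins, function(w) isTRUE(w$hotspot), TRUE)
  expect_equal(which(flagged), c(2L, 4L))

  # pipeline-side recovery at a threshold between base and planted density
  cm <- chromosome_class_map("A1", "AUTOSOME")
  sites <- read_vcf(fx$vcf, cm)
  grid <- window_grid(c(A1 = 5e5), 1e5)
  counts <- bin_variants(sites, grid)
  base_mu <- 15 * sum(1 / (1:19))  # E[S] per unplanted window
  hs <- find_hotspots(counts, snp_threshold = ceiling(4 * base_mu),
                      indel_threshold = 2000)
  expect_equal(which(hs$hotspot_snp), c(2L, 4L))
})
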