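test_that("site heterozygosity matches pair enumeration", {
  expect_equal(site_heterozygosity(2, 1), 1)
  expect_equal(site_heterozygosity(4, 0), 0)

  # an=10, ac=3: enumerate all 45 unordered allele pairs
  alleles <- c(rep(1, 3), rep(0, 7))
  pairs <- utils::combn(10, 2)
  frac_unequal <- mean(alleles[pairs[1, ]] != alleles[pairs[2, ]])
  expect_equal(site_heterozygosity(10, 3), frac_unequal)
  expect_equal(site_heterozygosity(10, 3), 7 / 15)

  # multiallelic: sums per-alt terms
  expect_equal(site_heterozygosity(6, c(1, 3)),
               (2 * 1 * 5 + 2 * 3 * 3) / 30)

  skipped <- site_heterozygosity(1, 0)
  expect_true(is.na(skipped) && isTRUE(attr(skipped, "skipped")))
  expect_error(site_heterozygosity(4, 5), "outside")
})

test_that("windowed pi equals brute-force pairwise differences (identity)", {
  expect_equal(as.numeric(window_pi_standard(NULL, 100)), 0)
  one <- make_sites("c1", 50, an = 2L, ac = 1L)
  expect_equal(as.numeric(window_pi_standard(one, 100)), 0.01)

  set.seed(101)
  for (rep in 1:100) {
    n <- sample(4:12, 1)
    s <- sample(5:60, 1)
    gm <- rand_gm(n, s)
    sites <- sites_from_gm(gm)
    wlen <- 1000
    expect_equal(as.numeric(window_pi_standard(sites, wlen)),
                 oracle_pairwise(gm) / wlen, tolerance = 1e-9)
    expect_equal(mean_pairwise_diff(gm), oracle_pairwise(gm),
                 tolerance = 1e-12)
  }
})

test_that("mean pairwise difference handles the degenerate cases", {
  expect_equal(mean_pairwise_diff(rbind(c(0, 0), c(0, 0))), 0)
  expect_equal(mean_pairwise_diff(rbind(c(0, 0), c(1, 1))), 2)
  expect_error(mean_pairwise_diff(matrix(0, 1, 3)), "2 sequences")
  expect_error(mean_pairwise_diff(rbind(c(0, NA), c(1, 1))), "missing")
})

test_that("the alternative ratio-form pi evaluates verbatim and is flagged", {
  expect_equal(window_pi_alt(an = 4, ac = 1, w = 100, k = 1), 2)
  empty <- window_pi_alt(an = numeric(0), ac = numeric(0), w = 100, k = 0)
  expect_true(is.na(empty) && isTRUE(attr(empty, "undefined")))
  # generally disagrees with the standard estimator on the same window
  sites <- make_sites("c1", c(10, 20), an = 4L, ac = c(1L, 2L))
  std <- as.numeric(window_pi_standard(sites, 100))
  alt <- window_pi_alt(an = c(4, 4), ac = c(1, 2), w = 100, k = 2)
  expect_false(isTRUE(all.equal(std, alt)))
})

test_that("Watterson's theta follows the harmonic-sum form", {
  expect_equal(watterson_theta(0, 10), 0)
  expect_equal(watterson_theta(5, 2), 5)
  expect_equal(watterson_theta(10, 5), 10 / (1 + 1 / 2 + 1 / 3 + 1 / 4))
  expect_equal(watterson_theta(10, 5), 4.8)
  expect_error(watterson_theta(3, 1), ">= 2")
})

test_that("Tajima's D matches the hand-computed worked example and oracle", {
  # numerator zero
  a1 <- sum(1 / (1:9))
  expect_equal(tajima_d(5, 10, 5 / a1), 0)

  # 4 samples, 3 segregating sites:
  # 000 / 100 / 110 / 111 -> per-site ac 3, 2, 1; theta_pi = 5/3
  gm <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(1, 1, 1))
  tpi <- mean_pairwise_diff(gm)
  expect_equal(tpi, 5 / 3)
  d <- tajima_d(3, 4, tpi)
  expect_equal(d, oracle_tajima(3, 4, 5 / 3), tolerance = 1e-12)
  expect_equal(d, 0.1676558, tolerance = 1e-6)

  # undefined cases are NA, never zero
  expect_true(is.na(tajima_d(0, 10, 0)))
  expect_true(is.na(tajima_d(3, 1, 1)))

  # 25 random (S, n, theta_pi) triples against the independent textbook form
  set.seed(7)
  for (i in 1:25) {
    S <- sample(1:80, 1)
    n <- sample(3:60, 1)
    tpi <- stats::runif(1, 0, S)
    expect_equal(as.numeric(tajima_d(S, n, tpi)), oracle_tajima(S, n, tpi),
                 tolerance = 1e-12)
  }
})

test_that("Ka/Ks modes and undefined handling", {
  expect_equal(ka_ks(10, 5), 2)
  expect_equal(ka_ks(7, 7, mode = "per_site",
                     sites_nonsyn = 100, sites_syn = 100), 1)
  und <- ka_ks(3, 0)
  expect_true(is.na(und) && isTRUE(attr(und, "undefined")))
  expect_error(ka_ks(1, 1, mode = "per_site"), "requires")
})

test_that("NG86 site counts match exhaustive codon enumeration", {
  # TTT (Phe): only TTC at position 3 is synonymous -> 1/3 synonymous site
  res <- ng86_site_counts("TTT")
  expect_equal(res$sites_syn, 1 / 3)
  expect_equal(res$sites_nonsyn + res$sites_syn, 3)

  # ATGATG: brute force over all 18 single-base mutants
  code <- Biostrings::GENETIC_CODE
  brute <- function(cds) {
    syn <- 0
    for (i in seq(1, nchar(cds), 3)) {
      codon <- strsplit(substr(cds, i, i + 2), "")[[1]]
      for (p in 1:3) {
        for (b in setdiff(c("A", "C", "G", "T"), codon[p])) {
          mut <- codon
          mut[p] <- b
          if (code[[paste(mut, collapse = "")]] ==
                code[[paste(codon, collapse = "")]]) {
            syn <- syn + 1 / 3
          }
        }
      }
    }
    syn
  }
  res2 <- ng86_site_counts("ATGATG")
  expect_equal(res2$sites_syn, brute("ATGATG"), tolerance = 1e-12)
  expect_equal(res2$sites_nonsyn + res2$sites_syn, 6)

  # per_site Ka/Ks consistent with enumeration-based opportunity
  cds <- "ATGTTTGGC"
  r <- ng86_site_counts(cds)
  expect_equal(r$sites_syn, brute(cds), tolerance = 1e-12)
  expect_equal(ka_ks(4, 2, mode = "per_site",
                     sites_nonsyn = r$sites_nonsyn, sites_syn = r$sites_syn),
               (4 / r$sites_nonsyn) / (2 / r$sites_syn))

  # conservation holds per codon for random stop-free CDS
  set.seed(5)
  codons <- setdiff(names(code)[code != "*"], NA)
  for (i in 1:10) {
    cds <- paste(sample(codons, 20, replace = TRUE), collapse = "")
    r <- ng86_site_counts(cds)
    expect_equal(r$sites_nonsyn + r$sites_syn, nchar(cds))
  }

  # ambiguous codons are skipped and counted
  amb <- ng86_site_counts("ATGNNT")
  expect_equal(amb$n_codons_skipped, 1L)
  expect_equal(amb$sites_nonsyn + amb$sites_syn, 3)
  expect_error(ng86_site_counts("ATGA"), "divisible")
})

test_that("window_stats assembles counts and estimators per window", {
  set.seed(20)
  gm <- rand_gm(8, 30, p = 0.4)
  sites <- sites_from_gm(gm)
  sites$pos <- sites$pos + 10L  # keep inside window 1
  sites$site_key <- paste0(sites$chrom, ":", sites$pos)
  grid <- window_grid(c(c1 = 200L), window_size = 100L)
  ws <- window_stats(sites, grid)
  expect_equal(nrow(ws), 2L)
  seg <- colSums(gm) > 0 & colSums(gm) < nrow(gm)
  expect_equal(ws$s_seg[1], sum(seg))
  expect_equal(ws$pi_std[1], mean_pairwise_diff(gm) / 100, tolerance = 1e-12)
  expect_equal(ws$tajima_d[1],
               oracle_tajima(sum(seg), 8, mean_pairwise_diff(gm)),
               tolerance = 1e-12)
  # empty window: NA statistics, zero pi
  expect_equal(ws$pi_std[2], 0)
  expect_true(is.na(ws$tajima_d[2]))
  expect_true(is.na(ws$theta_w[2]))
})
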