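# Independent oracles and fixture builders used across the suite.

# Random complete 0/1 genotype matrix (rows = chromosomes, cols = sites).
rand_gm <- function(n, s, p = NULL) {
  if (is.null(p)) p <- stats::runif(1, 0.1, 0.9)
  matrix(stats::rbinom(n * s, 1, p), nrow = n, ncol = s)
}

# Brute-force mean pairwise difference: explicit double loop over all pairs,
# written independently of the package's implementation.
oracle_pairwise <- function(gm) {
  n <- nrow(gm)
  tot <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      tot <- tot + sum(gm[i, ] != gm[j, ])
    }
  }
  tot / (n * (n - 1) / 2)
}

# Textbook Tajima (1989) D, re-derived from the published constants
# independently of the package code path.
oracle_tajima <- function(S, n, theta_pi) {
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  v <- (c1 / a1) * S + (c2 / (a1^2 + a2)) * S * (S - 1)
  if (v <= 0) return(NA_real_)   # D undefined at zero variance
  (theta_pi - S / a1) / sqrt(v)
}

# Per-alt site data.frame from a complete genotype matrix, positions 1..S.
sites_from_gm <- function(gm, chrom = "c1") {
  s <- ncol(gm)
  ac <- colSums(gm)
  data.frame(chrom = chrom, pos = seq_len(s),
             site_key = paste0(chrom, ":", seq_len(s)),
             ref = "A", alt = "G", an = nrow(gm), ac = ac,
             vclass = "SNP", indel_len = 0L,
             so_term = NA_character_, impact = NA_character_,
             sift = NA_real_, stringsAsFactors = FALSE)
}

# Minimal synthetic site table for window/summary tests.
make_sites <- function(chrom, pos, vclass = "SNP", indel_len = 0L,
                       an = 4L, ac = 1L, so_term = NA_character_,
                       sift = NA_real_, class = "AUTOSOME") {
  k <- length(pos)
  key <- if (k == 0) character(0) else paste0(rep_len(chrom, k), ":", pos)
  data.frame(chrom = rep_len(chrom, k), pos = pos,
             site_key = key,
             ref = rep_len("A", k), alt = rep_len("G", k),
             an = rep_len(an, k), ac = rep_len(ac, k),
             vclass = rep_len(vclass, k),
             indel_len = rep_len(as.integer(indel_len), k),
             so_term = rep_len(so_term, k),
             impact = rep_len(NA_character_, k),
             sift = rep_len(sift, k),
             class = rep_len(class, k),
             stringsAsFactors = FALSE)
}

# Hand-written five-site, three-sample VCF covering missing genotypes,
# multiallelic sites, haploid calls and an InDel; AN/AC in INFO are the hand
# counts.
write_mini_vcf <- function(path) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=10000>",
    "##contig=<ID=chrY,length=10000>",
    "##INFO=<ID=AN,Number=1,Type=Integer,Description=\"x\">",
    "##INFO=<ID=AC,Number=A,Type=Integer,Description=\"x\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"x\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "s1", "s2", "s3"), collapse = "\t"),
    "chr1\t100\t.\tA\tG\t.\tPASS\tAN=4;AC=3\tGT\t0/1\t1/1\t./.",
    "chr1\t200\t.\tA\tAT\t.\tPASS\tAN=6;AC=2\tGT\t0/1\t0/1\t0/0",
    "chr1\t300\t.\tA\tG,T\t.\tPASS\tAN=6;AC=2,3\tGT\t0/1\t1/2\t2/2",
    "chr1\t400\t.\tC\tA\t.\tPASS\tAN=6;AC=0\tGT\t0/0\t0/0\t0/0",
    "chrY\t500\t.\tT\tC\t.\tPASS\tAN=2;AC=1\tGT\t1\t0\t."
  )
  writeLines(lines, path)
  path
}

mini_class_map <- function() {
  chromosome_class_map(c("chr1", "chrY"), c("AUTOSOME", "Y"))
}

# Two small GFF3 files: three genes / two CDS in the first; the second
# repeats one gene identically and adds a gene on another chromosome.
write_mini_gffs <- function(dir) {
  g1 <- file.path(dir, "a.gff3")
  g2 <- file.path(dir, "b.gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t1000\t2000\t.\t+\t.\tID=g1",
    "chr1\tsrc\tCDS\t1200\t1400\t.\t+\t0\tID=g1_cds;Parent=g1",
    "chr1\tsrc\tgene\t3000\t4000\t.\t-\t.\tID=g2",
    "chr1\tsrc\tCDS\t3300\t3500\t.\t-\t0\tID=g2_cds;Parent=g2",
    "chr1\tsrc\tgene\t5000\t6000\t.\t+\t.\tID=g3"), g1)
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t1000\t2000\t.\t+\t.\tID=g1",
    "chrY\tsrc\tgene\t100\t900\t.\t+\t.\tID=gy1"), g2)
  list(g1 = g1, g2 = g2)
}
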