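#' Per-site heterozygosity from allele counts
#'
#' Unbiased probability that two alleles drawn without replacement from the
#' called genotypes at a site differ:
#' \deqn{h = \sum_{alt} \frac{2\,AC (AN - AC)}{AN (AN - 1)}}
#' where AN is the number of called alleles and AC the count of each
#' alternate allele. Summed over sites this equals the mean number of
#' pairwise differences (see [mean_pairwise_diff()]).
#'
#' @param an total number of called alleles at the site (>= 2).
#' @param acs numeric vector of per-alt allele counts.
#' @return The per-site heterozygosity, or `NA` with attribute `skipped` when
#'   `an < 2`.
#' @export
#' @examples
#' site_heterozygosity(2, 1)   # 1: the single pair differs
#' site_heterozygosity(10, 3)  # 2*3*7/90
site_heterozygosity <- function(an, acs) {
  if (an < 2) {
    out <- NA_real_
    attr(out, "skipped") <- TRUE
    return(out)
  }
  if (any(acs < 0) || any(acs > an)) stop("allele count outside [0, an]")
  sum(2 * acs * (an - acs)) / (an * (an - 1))
}

# Vectorised per-alt heterozygosity terms (used by window_stats).
.het_terms <- function(an, ac) {
  ifelse(an >= 2, 2 * ac * (an - ac) / (an * (an - 1)), NA_real_)
}

#' Windowed nucleotide diversity (standard allele-count estimator)
#'
#' Sum of per-site heterozygosity over the SNPs in a window, divided by the
#' window length: the conventional per-bp nucleotide diversity computed from
#' VCF allele counts (as in vcftools' windowed pi). Sites with fewer than two
#' called alleles are skipped and counted.
#'
#' @param sites data.frame of per-alt site rows (as from [read_vcf()]) whose
#'   positions fall inside the window; only rows with `vclass == "SNP"`
#'   contribute.
#' @param window_len window length in bp (> 0).
#' @return Nucleotide diversity per bp (0 for an empty window), with
#'   attribute `n_skipped_low_an`.
#' @export
window_pi_standard <- function(sites, window_len) {
  stopifnot(window_len > 0)
  if (is.null(sites) || nrow(sites) == 0) {
    out <- 0
    attr(out, "n_skipped_low_an") <- 0L
    return(out)
  }
  snp <- sites[!is.na(sites$vclass) & sites$vclass == "SNP", , drop = FALSE]
  if (nrow(snp) == 0) {
    out <- 0
    attr(out, "n_skipped_low_an") <- 0L
    return(out)
  }
  terms <- .het_terms(snp$an, snp$ac)
  skipped <- is.na(terms)
  out <- sum(terms[!skipped]) / window_len
  attr(out, "n_skipped_low_an") <-
    length(unique(snp$site_key[skipped]))
  out
}

#' Windowed diversity, alternative ratio form
#'
#' Evaluates verbatim a ratio-form expression sometimes quoted for VCF-based
#' windowed diversity:
#' \deqn{\hat\pi_{alt} = \frac{\sum_i AN_i(AN_i-1) + (w-k)\,p}
#'                            {2\sum_i AC_i(AN_i - AC_i)}}
#' with k variants in a window of size w and a pairwise-comparison term p.
#' As written this is dimensionally inconsistent with conventional per-bp
#' diversity (the allele-count products appear inverted), so the value is
#' emitted for reference only and never drives downstream comparisons;
#' [window_pi_standard()] is the working estimator.
#'
#' @param an per-site AN values (one per variant site; length k).
#' @param ac per-alt AC values; `ac_an` supplies the matching AN for each
#'   entry (defaults to `an`, the biallelic case).
#' @param w window size in bp.
#' @param k number of variants in the window (defaults to `length(an)`).
#' @param p pairwise window-comparison term (default 0).
#' @param ac_an AN matched to each `ac` entry.
#' @return The ratio, or `NA` with attribute `undefined = TRUE` when the
#'   denominator is zero (e.g. k = 0 or all sites monomorphic).
#' @export
#' @examples
#' window_pi_alt(an = 4, ac = 1, w = 100, k = 1)  # (4*3)/(2*1*3) = 2
window_pi_alt <- function(an, ac, w, k = length(an), p = 0, ac_an = an) {
  stopifnot(length(ac) == length(ac_an))
  den <- 2 * sum(ac * (ac_an - ac))
  if (den == 0) {
    out <- NA_real_
    attr(out, "undefined") <- TRUE
    return(out)
  }
  (sum(an * (an - 1)) + (w - k) * p) / den
}

#' Mean pairwise difference over a complete genotype matrix
#'
#' Brute-force average number of differences between all pairs of sequences:
#' \deqn{\hat\theta_\pi = \sum_{i<j} d_{ij} / \binom{n}{2}.}
#' Used as the exact oracle for the allele-count estimator; on complete data
#' the two are algebraically identical.
#'
#' @param gm numeric matrix, rows = sequences (haploid chromosomes),
#'   columns = biallelic sites, entries 0/1 with no missing values.
#' @return Mean pairwise difference (count scale, not per bp).
#' @export
mean_pairwise_diff <- function(gm) {
  gm <- as.matrix(gm)
  n <- nrow(gm)
  if (n < 2) stop("need at least 2 sequences")
  if (anyNA(gm)) stop("missing calls not allowed in the oracle substrate")
  if (ncol(gm) == 0) return(0)
  sum(stats::dist(gm, method = "manhattan")) / (n * (n - 1) / 2)
}

# Harmonic-number helpers for Watterson / Tajima constants.
.a1 <- function(n) sum(1 / seq_len(n - 1))
.a2 <- function(n) sum(1 / seq_len(n - 1)^2)

#' Watterson's theta
#'
#' \deqn{\hat\theta_W = S / \sum_{i=1}^{n-1} 1/i}
#'
#' @param S number of segregating sites (>= 0).
#' @param n number of sampled chromosomes (>= 2).
#' @return Watterson's estimator on the same (count) scale as S.
#' @export
#' @examples
#' watterson_theta(10, 5)  # 10 / (1 + 1/2 + 1/3 + 1/4) = 4.8
watterson_theta <- function(S, n) {
  if (n < 2) stop("n must be >= 2")
  if (S < 0) stop("S must be >= 0")
  S / .a1(n)
}

#' Tajima's D
#'
#' Standardised difference between the pairwise estimator and Watterson's
#' estimator, with the standard Tajima (1989) variance:
#' \deqn{D = \frac{\hat\theta_\pi - S/a_1}{\sqrt{e_1 S + e_2 S(S-1)}}}
#' where \eqn{a_1 = \sum 1/i}, \eqn{a_2 = \sum 1/i^2},
#' \eqn{b_1 = (n+1)/(3(n-1))}, \eqn{b_2 = 2(n^2+n+3)/(9n(n-1))},
#' \eqn{c_1 = b_1 - 1/a_1}, \eqn{c_2 = b_2 - (n+2)/(a_1 n) + a_2/a_1^2},
#' \eqn{e_1 = c_1/a_1}, \eqn{e_2 = c_2/(a_1^2 + a_2)}.
#' Negative D indicates an excess of rare variants (expansion, or purifying /
#' positive selection); positive D an excess of intermediate frequencies
#' (contraction or balancing selection).
#'
#' @param S number of segregating sites.
#' @param n number of sampled chromosomes.
#' @param theta_pi mean pairwise differences for the same window (count
#'   scale).
#' @return D, or `NA` (never 0) when undefined: S < 1, n < 2, or a
#'   non-positive variance term.
#' @export
tajima_d <- function(S, n, theta_pi) {
  if (is.na(S) || is.na(n) || is.na(theta_pi)) return(NA_real_)
  if (S < 1 || n < 2) return(NA_real_)
  a1 <- .a1(n)
  a2 <- .a2(n)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  v <- e1 * S + e2 * S * (S - 1)
  if (v <= 0) {
    out <- NA_real_
    attr(out, "undefined_variance") <- TRUE
    return(out)
  }
  (theta_pi - S / a1) / sqrt(v)
}

#' Ka/Ks selection-pressure ratio
#'
#' Ratio of nonsynonymous to synonymous variation. In `count_ratio` mode the
#' raw count ratio \eqn{K_a/K_s = n_{nonsyn}/n_{syn}} is returned (the usage
#' behind per-chromosome comparisons of annotated SNP counts); in `per_site`
#' mode counts are first normalised by the mutational opportunity of the
#' coding sequence (see [ng86_site_counts()]). A ratio above 1 is read as
#' positive selection, below 1 as purifying selection; it is never negative.
#'
#' @param n_nonsyn count of nonsynonymous SNPs.
#' @param n_syn count of synonymous SNPs.
#' @param mode `"count_ratio"` (default) or `"per_site"`.
#' @param sites_nonsyn,sites_syn per-site denominators, required for
#'   `per_site`.
#' @return The ratio, or `NA` (reported as undefined, never `Inf`) when
#'   `n_syn == 0`.
#' @export
#' @examples
#' ka_ks(10, 5)  # 2
ka_ks <- function(n_nonsyn, n_syn, mode = c("count_ratio", "per_site"),
                  sites_nonsyn = NULL, sites_syn = NULL) {
  mode <- match.arg(mode)
  stopifnot(n_nonsyn >= 0, n_syn >= 0)
  if (n_syn == 0) {
    out <- NA_real_
    attr(out, "undefined") <- TRUE
    return(out)
  }
  if (mode == "count_ratio") {
    return(n_nonsyn / n_syn)
  }
  if (is.null(sites_nonsyn) || is.null(sites_syn)) {
    stop("per_site mode requires sites_nonsyn and sites_syn")
  }
  if (sites_nonsyn <= 0 || sites_syn <= 0) stop("site denominators must be > 0")
  (n_nonsyn / sites_nonsyn) / (n_syn / sites_syn)
}

#' Nei-Gojobori (1986) synonymous / nonsynonymous site counts
#'
#' For each codon, each of the three positions contributes the fraction of
#' its three possible single-base changes that are synonymous (weight 1/3
#' each) to the synonymous site total, and the complement to the
#' nonsynonymous total; changes to or from stop codons count as
#' nonsynonymous unless both codons are stops. Codons containing ambiguous
#' bases are skipped and counted. Totals sum to the number of scored bases.
#'
#' @param cds_sequence character scalar, CDS nucleotide sequence whose length
#'   is divisible by 3 (standard genetic code).
#' @return list with `sites_nonsyn`, `sites_syn` and `n_codons_skipped`.
#' @export
#' @examples
#' ng86_site_counts("TTT")  # third position 1/3 synonymous (TTC)
ng86_site_counts <- function(cds_sequence) {
  s <- toupper(as.character(cds_sequence))
  if (nchar(s) %% 3 != 0) stop("CDS length must be divisible by 3")
  code <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T")
  syn <- 0
  nonsyn <- 0
  skipped <- 0L
  for (i in seq(1, nchar(s), by = 3)) {
    codon <- substr(s, i, i + 2)
    cb <- strsplit(codon, "")[[1]]
    if (!all(cb %in% bases)) {
      skipped <- skipped + 1L
      next
    }
    aa <- code[[codon]]
    for (p in 1:3) {
      for (b in setdiff(bases, cb[p])) {
        mut <- cb
        mut[p] <- b
        aa2 <- code[[paste(mut, collapse = "")]]
        if (identical(aa, aa2)) syn <- syn + 1 / 3 else nonsyn <- nonsyn + 1 / 3
      }
    }
  }
  list(sites_nonsyn = nonsyn, sites_syn = syn, n_codons_skipped = skipped)
}

#' Per-window population-genetic statistics
#'
#' Joins binned variants with the estimators: per window, SNP/InDel counts,
#' segregating sites S, nucleotide diversity (standard and alternative ratio
#' form), Watterson's theta and Tajima's D. The sample size n for Watterson /
#' Tajima is the mean AN over the window's segregating SNP sites rounded to
#' the nearest integer (AN varies by site when genotypes are missing).
#' Undefined statistics are `NA`, never 0.
#'
#' @param sites per-alt site data.frame from [read_vcf()].
#' @param grid window grid from [window_grid()].
#' @param p pairwise-comparison term forwarded to [window_pi_alt()].
#' @return The grid with columns `n_snp`, `n_indel`, `s_seg`, `pi_std`,
#'   `pi_alt`, `theta_w`, `tajima_d`, `n_chrom_mean` appended.
#' @export
window_stats <- function(sites, grid, p = 0) {
  wsize <- attr(grid, "window_size")
  counts <- bin_variants(sites, grid)
  idx <- .assign_windows(sites, grid)
  out <- counts
  ns <- nrow(grid)
  s_seg <- integer(ns)
  pi_std <- numeric(ns)
  pi_alt <- rep(NA_real_, ns)
  theta_w <- rep(NA_real_, ns)
  taj <- rep(NA_real_, ns)
  n_mean <- rep(NA_real_, ns)
  for (w in seq_len(ns)) {
    sw <- sites[!is.na(idx) & idx == w, , drop = FALSE]
    wlen <- grid$end[w] - grid$start[w] + 1L
    pi_std[w] <- as.numeric(window_pi_standard(sw, wlen))
    snp <- sw[!is.na(sw$vclass) & sw$vclass == "SNP" & sw$an >= 2, ,
              drop = FALSE]
    seg_keys <- unique(snp$site_key[snp$ac > 0 & snp$ac < snp$an])
    S <- length(seg_keys)
    s_seg[w] <- S
    if (S > 0) {
      seg <- snp[snp$site_key %in% seg_keys, , drop = FALSE]
      site_an <- tapply(seg$an, seg$site_key, function(x) x[1])
      n <- round(mean(site_an))
      n_mean[w] <- mean(site_an)
      theta_pi <- sum(.het_terms(seg$an, seg$ac))
      if (n >= 2) {
        theta_w[w] <- watterson_theta(S, n)
        taj[w] <- tajima_d(S, n, theta_pi)
      }
      pi_alt[w] <- as.numeric(window_pi_alt(
        an = unname(site_an), ac = seg$ac, w = wsize,
        k = S, p = p, ac_an = seg$an))
    } else {
      pi_alt[w] <- NA_real_
    }
  }
  out$s_seg <- s_seg
  out$pi_std <- pi_std
  out$pi_alt <- pi_alt
  out$theta_w <- theta_w
  out$tajima_d <- taj
  out$n_chrom_mean <- n_mean
  out
}
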