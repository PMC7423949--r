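#' Packaged ARS-UCD1.2_Btau5.0.1Y chromosome table
#'
#' Chromosome lengths, gene counts and the published genes-per-Mbp ratios of
#' the cattle reference assembly (29 autosomes, X and Y), shipped as a
#' plain-text fixture so that descriptive summaries can be validated
#' self-containedly.
#'
#' @return data.frame `chrom`, `class`, `length_bp`, `n_genes`,
#'   `genes_per_mbp_printed`.
#' @export
bovine_chromosome_table <- function() {
  path <- system.file("extdata", "arsucd12_btau501y_chromosomes.tsv",
                      package = "karyodiv", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c("character", "character", "numeric",
                                   "integer", "numeric"))
}

#' Published whole-genome variant counts for the cattle cohort
#'
#' Headline variant counts reported for a 217-animal whole-genome
#' resequencing cohort aligned to ARS-UCD1.2_Btau5.0.1Y, used as printed
#' inputs for ratio summaries (SNP/InDel shares, genome-wide SNP fraction,
#' Y-chromosome SNP density).
#'
#' @return Named numeric vector.
#' @export
bovine_cohort_counts <- function() {
  path <- system.file("extdata", "bovine_cohort_variant_counts.tsv",
                      package = "karyodiv", mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(df$value, df$quantity)
}

#' Chromosome-level descriptive summary
#'
#' Computes per-chromosome gene density and variant densities:
#' `genes_per_mbp = n_genes / (length / 1e6)`,
#' `snp_density_pct = 100 * n_snp / length` (the percent of the chromosome
#' length covered by SNPs) and likewise for InDels. Values are kept at full
#' precision; rounding is left to the presentation layer.
#'
#' @param lengths named numeric vector of chromosome lengths (bp, > 0).
#' @param n_genes named integer vector of gene counts per chromosome.
#' @param n_snp,n_indel named counts per chromosome (default 0).
#' @param class_map class map covering every chromosome.
#' @param kaks optional named numeric vector of Ka/Ks ratios.
#' @return data.frame `chrom`, `class`, `length_bp`, `n_genes`,
#'   `genes_per_mbp`, `n_snp`, `n_indel`, `snp_density_pct`,
#'   `indel_density_pct`, `ka_ks`.
#' @export
chromosome_summary <- function(lengths, n_genes, n_snp = NULL, n_indel = NULL,
                               class_map = NULL, kaks = NULL) {
  chroms <- names(lengths)
  if (is.null(chroms)) stop("lengths must be named by chromosome")
  if (any(lengths <= 0)) stop("zero or negative chromosome length")
  pick <- function(v) {
    if (is.null(v)) return(stats::setNames(rep(0, length(chroms)), chroms))
    if (!all(chroms %in% names(v))) stop("missing chromosome in input vector")
    v[chroms]
  }
  ng <- pick(n_genes)
  ns <- pick(n_snp)
  ni <- pick(n_indel)
  kk <- if (is.null(kaks)) rep(NA_real_, length(chroms)) else
    unname(kaks[chroms])
  cls <- if (is.null(class_map)) rep(NA_character_, length(chroms)) else {
    .check_chroms_in_map(chroms, class_map, "summary")
    unname(class_map[chroms])
  }
  data.frame(
    chrom = chroms, class = cls,
    length_bp = unname(lengths),
    n_genes = unname(ng),
    genes_per_mbp = unname(ng / (lengths / 1e6)),
    n_snp = unname(ns), n_indel = unname(ni),
    snp_density_pct = unname(100 * ns / lengths),
    indel_density_pct = unname(100 * ni / lengths),
    ka_ks = kk,
    stringsAsFactors = FALSE)
}

#' Per-class InDel length summary
#'
#' Summarises InDel length distributions per chromosome class: minimum,
#' maximum, mode (most frequent length), median, and the fraction of InDels
#' at least 10 bp long. Classes without InDels are absent from the output.
#'
#' @param sites per-alt site data.frame (uses rows with `vclass == "InDel"`),
#'   or a data.frame with `indel_len` and `class` columns.
#' @return data.frame `class`, `n`, `min`, `max`, `mode`, `median`,
#'   `frac_ge_10bp`.
#' @export
indel_length_summary <- function(sites) {
  ind <- sites[!is.na(sites$vclass) & sites$vclass == "InDel", , drop = FALSE]
  if (nrow(ind) == 0) {
    return(data.frame(class = character(), n = integer(), min = integer(),
                      max = integer(), mode = integer(), median = numeric(),
                      frac_ge_10bp = numeric(), stringsAsFactors = FALSE))
  }
  out <- lapply(split(ind$indel_len, ind$class), function(l) {
    tab <- table(l)
    data.frame(n = length(l), min = min(l), max = max(l),
               mode = as.integer(names(tab)[which.max(tab)]),
               median = stats::median(l),
               frac_ge_10bp = mean(l >= 10))
  })
  res <- do.call(rbind, out)
  res <- cbind(class = names(out), res)
  rownames(res) <- NULL
  res
}

#' Variant density in coding vs non-coding regions
#'
#' Splits each chromosome into merged CDS intervals and the remainder, and
#' reports the number of variant sites falling in each together with the
#' per-length percentage `100 * n_variants / region_length`. A variant is
#' CDS iff its position lies inside the merged CDS intervals; CDS and
#' non-CDS region lengths sum to the chromosome length and the two variant
#' counts sum to the total.
#'
#' @param sites per-alt site data.frame from [read_vcf()].
#' @param genes GeneSet list from [read_gff_merged()] (uses `$cds`).
#' @param lengths named chromosome lengths (bp).
#' @return data.frame `chrom`, `region` (`CDS`/`NON_CDS`),
#'   `total_region_len`, `n_variants`, `per_len_pct`.
#' @export
region_density <- function(sites, genes, lengths) {
  cds <- if (is.list(genes) && !is.data.frame(genes)) genes$cds else genes
  out <- list()
  for (ch in names(lengths)) {
    len <- lengths[[ch]]
    ci <- cds[cds$chrom == ch, , drop = FALSE]
    cds_len <- 0L
    in_cds <- function(pos) rep(FALSE, length(pos))
    if (nrow(ci) > 0) {
      red <- IRanges::reduce(IRanges::IRanges(ci$start, ci$end))
      cds_len <- sum(IRanges::width(red))
      in_cds <- function(pos) {
        IRanges::overlapsAny(IRanges::IRanges(pos, pos), red)
      }
    }
    si <- sites[sites$chrom == ch, , drop = FALSE]
    pos <- unique(si$pos)
    n_in <- sum(in_cds(pos))
    n_out <- length(pos) - n_in
    out[[ch]] <- data.frame(
      chrom = ch, region = c("CDS", "NON_CDS"),
      total_region_len = c(cds_len, len - cds_len),
      n_variants = c(n_in, n_out),
      per_len_pct = 100 * c(
        if (cds_len > 0) n_in / cds_len else NA_real_,
        n_out / (len - cds_len)),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Consequence-term profile of variants in transcription regions
#'
#' Percent of variants per Sequence Ontology consequence term, within each
#' chromosome class, among variants carrying a gene-associated term
#' (intergenic variants are excluded). One consequence per variant as
#' assigned by the upstream annotator; the profile is invariant to record
#' order.
#'
#' @param sites per-alt site data.frame with `so_term` and `class`.
#' @return data.frame `class`, `so_term`, `n`, `pct`.
#' @export
impact_profile <- function(sites) {
  keep <- !is.na(sites$so_term) & sites$so_term != "intergenic_variant"
  s <- sites[keep, , drop = FALSE]
  if (nrow(s) == 0) {
    return(data.frame(class = character(), so_term = character(),
                      n = integer(), pct = numeric(),
                      stringsAsFactors = FALSE))
  }
  # one consequence per variant site
  s <- s[!duplicated(s$site_key), , drop = FALSE]
  tab <- as.data.frame(table(class = s$class, so_term = s$so_term),
                       stringsAsFactors = FALSE)
  tab <- tab[tab$Freq > 0, , drop = FALSE]
  totals <- tapply(tab$Freq, tab$class, sum)
  tab$pct <- 100 * tab$Freq / as.numeric(totals[tab$class])
  names(tab)[names(tab) == "Freq"] <- "n"
  tab <- tab[order(tab$class, -tab$n), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' SIFT score classification
#'
#' Partitions variants with SIFT scores into deleterious (score <= threshold,
#' boundary inclusive: a score of exactly 0.05 is deleterious) and tolerated
#' (> threshold). Scores outside [0, 1] are rejected and counted.
#'
#' @param sites per-alt site data.frame with `sift` and `class` columns (rows
#'   without a score are ignored).
#' @param threshold deleterious threshold (default 0.05).
#' @return data.frame `class`, `n_deleterious`, `n_tolerated`; the retained
#'   per-class score vectors are in attribute `scores` (for rank tests) and
#'   the rejection count in attribute `n_rejected`.
#' @export
sift_classes <- function(sites, threshold = 0.05) {
  s <- sites[!is.na(sites$sift), , drop = FALSE]
  bad <- s$sift < 0 | s$sift > 1
  n_rej <- sum(bad)
  s <- s[!bad, , drop = FALSE]
  if (nrow(s) == 0) {
    out <- data.frame(class = character(), n_deleterious = integer(),
                      n_tolerated = integer(), stringsAsFactors = FALSE)
    attr(out, "scores") <- list()
    attr(out, "n_rejected") <- n_rej
    return(out)
  }
  spl <- split(s$sift, s$class)
  out <- data.frame(
    class = names(spl),
    n_deleterious = vapply(spl, function(x) sum(x <= threshold), 0L),
    n_tolerated = vapply(spl, function(x) sum(x > threshold), 0L),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "scores") <- spl
  attr(out, "n_rejected") <- n_rej
  out
}

#' Fold coverage of a sequencing run
#'
#' `coverage = R * L / G`: total aligned reads times mean read length over
#' genome size.
#'
#' @param R total number of aligned reads (>= 0).
#' @param L average read length (> 0).
#' @param G genome size in bp (> 0).
#' @return Fold coverage.
#' @export
#' @examples
#' coverage_fold(1e6, 100, 1e7)  # 10x
coverage_fold <- function(R, L, G) {
  if (G <= 0) stop("genome size must be > 0")
  if (L <= 0) stop("read length must be > 0")
  if (R < 0) stop("read count must be >= 0")
  R * L / G
}
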