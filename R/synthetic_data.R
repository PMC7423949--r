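#' Demography specifications for the coalescent simulator
#'
#' Single-step piecewise-constant population-size histories, expressed
#' relative to the present size (time runs backwards in coalescent units of
#' 2N0 generations). `EXPANSION(factor, onset)` means the population grew by
#' `factor` at `onset` (the ancestral epoch is `1/factor` of the present
#' size), producing an excess of rare variants and negative Tajima's D;
#' `CONTRACTION(factor, onset)` is the reverse (ancestral epoch `factor`
#' times the present size), producing positive D.
#'
#' @param factor size-change factor (> 1).
#' @param onset time of the change, coalescent units (> 0).
#' @return A demography list with `type`, and for non-constant histories
#'   `factor`, `onset` and the ancestral relative size `lambda_anc`.
#' @export
demography_constant <- function() {
  structure(list(type = "CONSTANT"), class = "karyodiv_demography")
}

#' @rdname demography_constant
#' @export
demography_expansion <- function(factor = 10, onset = 0.1) {
  if (factor <= 1 || onset <= 0) stop("invalid demography parameters")
  structure(list(type = "EXPANSION", factor = factor, onset = onset,
                 lambda_anc = 1 / factor), class = "karyodiv_demography")
}

#' @rdname demography_constant
#' @export
demography_contraction <- function(factor = 10, onset = 0.1) {
  if (factor <= 1 || onset <= 0) stop("invalid demography parameters")
  structure(list(type = "CONTRACTION", factor = factor, onset = onset,
                 lambda_anc = factor), class = "karyodiv_demography")
}

# Waiting time to the next coalescence for k lineages at time t under a
# piecewise-constant relative size lambda(t); inverse-hazard sampling.
.coal_wait <- function(t, k, demography) {
  rate <- k * (k - 1) / 2
  E <- stats::rexp(1)
  if (demography$type == "CONSTANT") return(E / rate)
  onset <- demography$onset
  lam_anc <- demography$lambda_anc
  if (t >= onset) return(E * lam_anc / rate)
  H1 <- rate * (onset - t)           # hazard available before the size change
  if (E <= H1) E / rate else (onset - t) + (E - H1) * lam_anc / rate
}

# Coalescent tree as a list of intervals; each interval records its duration
# and the leaf membership of every active lineage, which is all that is
# needed to drop infinite-sites mutations.
.simulate_coalescent <- function(n, demography) {
  lineages <- lapply(seq_len(n), identity)
  k <- n
  t <- 0
  ints <- vector("list", n - 1)
  for (i in seq_len(n - 1)) {
    dt <- .coal_wait(t, k, demography)
    ints[[i]] <- list(dt = dt, k = k, lineages = lineages)
    pair <- sample.int(k, 2)
    merged <- c(lineages[[pair[1]]], lineages[[pair[2]]])
    lineages <- c(lineages[-pair], list(merged))
    k <- k - 1
    t <- t + dt
  }
  ints
}

#' Simulate one window of genotypes under the neutral coalescent
#'
#' Standard neutral coalescent with infinite-sites mutation: exponential
#' coalescence times (rescaled under a step demography), mutations dropped on
#' the tree as Poisson(theta/2 x total branch length), each creating one
#' biallelic segregating site carried by the leaves below it. Under a
#' constant size the expected number of segregating sites is
#' \eqn{E[S] = \theta \sum_{i=1}^{n-1} 1/i}. Deterministic given `seed`.
#'
#' @param theta scaled mutation rate per window (> 0).
#' @param n_chrom number of sampled chromosomes (>= 2).
#' @param demography from [demography_constant()] and friends.
#' @param seed optional integer; when supplied the RNG is seeded locally.
#' @return list with `genotypes` (0/1 matrix, `n_chrom` rows x S columns),
#'   `S`, `n` and `tree_length`.
#' @export
simulate_window_genotypes <- function(theta, n_chrom,
                                      demography = demography_constant(),
                                      seed = NULL) {
  if (theta <= 0) stop("theta must be > 0")
  if (n_chrom < 2) stop("need at least 2 chromosomes")
  if (!inherits(demography, "karyodiv_demography")) {
    stop("invalid demography object")
  }
  if (!is.null(seed)) set.seed(seed)
  ints <- .simulate_coalescent(n_chrom, demography)
  dt <- vapply(ints, `[[`, 0, "dt")
  kk <- vapply(ints, `[[`, 0, "k")
  total_len <- sum(dt * kk)
  S <- stats::rpois(1, theta / 2 * total_len)
  gm <- matrix(0L, nrow = n_chrom, ncol = S)
  if (S > 0) {
    wi <- sample.int(length(ints), S, replace = TRUE, prob = dt * kk)
    for (s in seq_len(S)) {
      int <- ints[[wi[s]]]
      carrier <- int$lineages[[sample.int(int$k, 1)]]
      gm[carrier, s] <- 1L
    }
  }
  list(genotypes = gm, S = S, n = n_chrom, tree_length = total_len)
}

#' Define a simulation scenario
#'
#' Bundles everything [emit_fixture()] needs to write a self-contained
#' FASTA / GFF3 / VCF fixture with known truth: sample sizes and sex
#' composition, per-chromosome class and length, the per-window mutation
#' parameter with effective-size scaling (autosome : X : Y = 1 : 3/4 : 1/4 by
#' default, the equal-sex-ratio expectation), demography, gene density, an
#' N-run gap plan and InDel settings. A seed is mandatory: the generator has
#' no hidden randomness and identical scenarios produce byte-identical files.
#'
#' @param seed integer RNG seed (required).
#' @param n_diploid_samples number of diploid individuals.
#' @param n_male how many of them are male (only males carry Y).
#' @param chrom_lengths named vector of chromosome lengths (bp).
#' @param chrom_classes named map of the same chromosomes to
#'   AUTOSOME/X/Y.
#' @param theta_autosome scaled mutation rate per window on autosomes.
#' @param ne_scaling per-class multipliers applied to `theta_autosome`.
#' @param demography demography shared by all chromosomes.
#' @param genes_per_mbp planted gene density.
#' @param gap_plan named list of N-run lengths (bp) per chromosome.
#' @param indel_fraction fraction of variant sites emitted as InDels.
#' @param indel_geom_p geometric parameter for InDel lengths
#'   (`len = 1 + rgeom(p)`); the default 0.35 gives modal length 1 and
#'   median 2.
#' @param window_size simulation window size (bp).
#' @param emit_annotation write SO/IMPACT/SIFT INFO fields.
#' @return A `sim_scenario` list.
#' @export
sim_scenario <- function(seed,
                         n_diploid_samples = 10,
                         n_male = 5,
                         chrom_lengths = c(A1 = 1e6, X = 1e6, Y = 1e6),
                         chrom_classes = c(A1 = "AUTOSOME", X = "X", Y = "Y"),
                         theta_autosome = 100,
                         ne_scaling = c(AUTOSOME = 1, X = 3 / 4, Y = 1 / 4),
                         demography = demography_constant(),
                         genes_per_mbp = 10,
                         gap_plan = list(Y = c(60000, 50000, 40000)),
                         indel_fraction = 0.137,
                         indel_geom_p = 0.35,
                         window_size = 100000,
                         emit_annotation = TRUE) {
  if (missing(seed)) stop("a seed is mandatory")
  stopifnot(n_male <= n_diploid_samples, n_male >= 1,
            n_diploid_samples >= 2,
            all(names(chrom_lengths) == names(chrom_classes)),
            theta_autosome > 0, window_size > 0,
            indel_fraction >= 0, indel_fraction < 1)
  for (ch in names(gap_plan)) {
    if (!ch %in% names(chrom_lengths)) stop("gap plan names unknown chromosome ", ch)
    if (sum(gap_plan[[ch]]) >= chrom_lengths[[ch]]) {
      stop("gap plan exceeds chromosome length on ", ch)
    }
  }
  structure(list(
    seed = as.integer(seed),
    n_diploid_samples = n_diploid_samples, n_male = n_male,
    chrom_lengths = chrom_lengths, chrom_classes = toupper(chrom_classes),
    theta_autosome = theta_autosome, ne_scaling = ne_scaling,
    demography = demography, genes_per_mbp = genes_per_mbp,
    gap_plan = gap_plan, indel_fraction = indel_fraction,
    indel_geom_p = indel_geom_p, window_size = as.integer(window_size),
    emit_annotation = emit_annotation,
    hotspot_multipliers = list()), class = "sim_scenario")
}

#' Plant a variant-density hotspot into a scenario
#'
#' Multiplies the mutation parameter of one window; the truth record emitted
#' alongside the fixture marks that window as a planted hotspot. A multiplier
#' of 1 returns the scenario unchanged.
#'
#' @param scenario a [sim_scenario()].
#' @param chrom chromosome name in the scenario.
#' @param window_index 1-based window number on that chromosome.
#' @param multiplier theta multiplier (>= 1).
#' @return The modified scenario.
#' @export
plant_hotspot <- function(scenario, chrom, window_index, multiplier) {
  stopifnot(inherits(scenario, "sim_scenario"), multiplier >= 1)
  if (!chrom %in% names(scenario$chrom_lengths)) {
    stop("unknown chromosome: ", chrom)
  }
  n_win <- ceiling(scenario$chrom_lengths[[chrom]] / scenario$window_size)
  if (window_index < 1 || window_index > n_win) {
    stop("unknown window ", window_index, " on ", chrom)
  }
  if (multiplier == 1) return(scenario)
  key <- as.character(window_index)
  mult <- scenario$hotspot_multipliers
  if (is.null(mult[[chrom]])) mult[[chrom]] <- numeric(0)
  mult[[chrom]][key] <- multiplier
  scenario$hotspot_multipliers <- mult
  scenario
}

# Place non-overlapping intervals of the given lengths uniformly on [1, L];
# rejection sampling with a deterministic RNG stream.
.place_intervals <- function(lengths, L, avoid = NULL, max_tries = 5000) {
  placed <- avoid
  out <- NULL
  for (len in lengths) {
    ok <- FALSE
    for (i in seq_len(max_tries)) {
      st <- sample.int(L - len + 1L, 1)
      en <- st + len - 1L
      clash <- FALSE
      if (!is.null(placed) && nrow(placed) > 0) {
        clash <- any(st <= placed$end & en >= placed$start)
      }
      if (!clash) {
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("could not place interval of length ", len,
                  " (plan too dense for chromosome length ", L, ")")
    row <- data.frame(start = st, end = en)
    placed <- rbind(placed, row)
    out <- rbind(out, row)
  }
  out
}

# SO consequence, impact and SIFT for one variant position given the planted
# annotation layout. Coding SNPs are missense:synonymous 2:1; SIFT scores are
# Beta-skewed low for deleterious draws, uniform above the threshold for
# tolerated ones.
.annotate_variant <- function(pos, is_snp, indel_len, genes, cds) {
  in_iv <- function(df) {
    nrow(df) > 0 && any(pos >= df$start & pos <= df$end)
  }
  so <- "intergenic_variant"
  if (in_iv(cds)) {
    if (is_snp) {
      so <- if (stats::runif(1) < 2 / 3) "missense_variant" else
        "synonymous_variant"
    } else {
      so <- if (indel_len %% 3 != 0) "frameshift_variant" else
        "inframe_indel"
    }
  } else if (in_iv(genes)) {
    so <- "intron_variant"
  } else if (nrow(genes) > 0 &&
             any(pos >= genes$start - 5000 & pos < genes$start)) {
    so <- "upstream_gene_variant"
  } else if (nrow(genes) > 0 &&
             any(pos > genes$end & pos <= genes$end + 5000)) {
    so <- "downstream_gene_variant"
  }
  impact <- switch(so,
                   frameshift_variant = "HIGH",
                   missense_variant = "MODERATE",
                   synonymous_variant = "LOW",
                   inframe_indel = "LOW",
                   "MODIFIER")
  sift <- NA_real_
  if (so == "missense_variant") {
    sift <- if (stats::runif(1) < 0.3) {
      round(0.05 * stats::rbeta(1, 1, 3), 4)
    } else {
      round(stats::runif(1, 0.051, 1), 4)
    }
  }
  list(so = so, impact = impact, sift = sift)
}

#' Emit a complete synthetic fixture
#'
#' Writes, into `outdir`: a reference FASTA with planted N-gap runs, a GFF3
#' with planted genes and CDS, a multi-sample VCF v4.2 with GT for every
#' sample (diploid on autosomes and X; haploid male-only calls on Y, females
#' emitted as missing), AN/AC INFO recomputed from the genotypes, optional
#' SO/IMPACT/SIFT annotation consistent with the planted gene layout, a
#' chromosome class map TSV, and a truth JSON recording per-window theta,
#' demography, expected Tajima's D sign and planted hotspot flags plus the
#' planted gene and gap intervals. Byte-identical across runs with the same
#' scenario.
#'
#' @param scenario a [sim_scenario()].
#' @param outdir output directory (created if needed).
#' @return list with paths `fasta`, `gff3`, `vcf`, `classes`, `truth` and the
#'   `truth` list itself (invisible).
#' @export
emit_fixture <- function(scenario, outdir) {
  stopifnot(inherits(scenario, "sim_scenario"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  set.seed(scenario$seed)
  sc <- scenario
  wsize <- sc$window_size
  samples <- sprintf("S%02d", seq_len(sc$n_diploid_samples))
  is_male <- seq_len(sc$n_diploid_samples) <= sc$n_male
  bases <- c("A", "C", "G", "T")

  fasta_lines <- character(0)
  gff_lines <- c("##gff-version 3")
  vcf_body <- character(0)
  contig_hdr <- character(0)
  truth_windows <- list()
  truth_genes <- list()
  truth_gaps <- list()
  seqs <- list()

  exp_sign <- switch(sc$demography$type,
                     CONSTANT = 0L, EXPANSION = -1L, CONTRACTION = 1L)

  for (ch in names(sc$chrom_lengths)) {
    L <- as.integer(sc$chrom_lengths[[ch]])
    cls <- sc$chrom_classes[[ch]]
    contig_hdr <- c(contig_hdr,
                    sprintf("##contig=<ID=%s,length=%d>", ch, L))

    seq_ch <- sample(bases, L, replace = TRUE)
    gaps <- NULL
    if (!is.null(sc$gap_plan[[ch]])) {
      gaps <- .place_intervals(sc$gap_plan[[ch]], L)
      for (i in seq_len(nrow(gaps))) {
        seq_ch[gaps$start[i]:gaps$end[i]] <- "N"
      }
      truth_gaps[[ch]] <- gaps
    }

    n_genes <- max(0L, round(sc$genes_per_mbp * L / 1e6))
    genes <- data.frame(start = integer(0), end = integer(0))
    cds <- data.frame(start = integer(0), end = integer(0))
    if (n_genes > 0) {
      glens <- sample(seq(2000L, 10000L, by = 100L), n_genes, replace = TRUE)
      genes <- .place_intervals(glens, L, avoid = gaps)
      genes$strand <- sample(c("+", "-"), n_genes, replace = TRUE)
      genes$id <- sprintf("%s_g%03d", ch, seq_len(n_genes))
      cds_rows <- list()
      for (i in seq_len(n_genes)) {
        clen <- 3L * sample(100:300, 1)
        clen <- min(clen, 3L * ((genes$end[i] - genes$start[i] - 1L) %/% 3L))
        cst <- genes$start[i] +
          sample.int(max(1L, genes$end[i] - genes$start[i] - clen), 1)
        cds_rows[[i]] <- data.frame(start = cst, end = cst + clen - 1L,
                                    gene_id = genes$id[i],
                                    strand = genes$strand[i])
      }
      cds <- do.call(rbind, cds_rows)
      for (i in seq_len(n_genes)) {
        gff_lines <- c(gff_lines, sprintf(
          "%s\tkaryodiv_sim\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
          ch, genes$start[i], genes$end[i], genes$strand[i], genes$id[i]))
        gff_lines <- c(gff_lines, sprintf(
          "%s\tkaryodiv_sim\tCDS\t%d\t%d\t.\t%s\t0\tID=%s_cds;Parent=%s",
          ch, cds$start[i], cds$end[i], cds$strand[i], genes$id[i],
          genes$id[i]))
      }
      truth_genes[[ch]] <- genes
    }

    n_chrom <- if (cls == "Y") sc$n_male else 2L * sc$n_diploid_samples
    theta_base <- sc$theta_autosome * sc$ne_scaling[[cls]]
    starts <- seq.int(1L, L, by = wsize)
    non_n <- seq_ch != "N"

    for (wi in seq_along(starts)) {
      wstart <- starts[wi]
      wend <- min(wstart + wsize - 1L, L)
      mult <- 1
      hm <- sc$hotspot_multipliers[[ch]]
      if (!is.null(hm) && as.character(wi) %in% names(hm)) {
        mult <- hm[[as.character(wi)]]
      }
      theta_w <- theta_base * mult
      avail <- which(non_n[wstart:wend]) + wstart - 1L
      sim <- simulate_window_genotypes(theta_w, n_chrom, sc$demography)
      S <- min(sim$S, length(avail))
      truth_windows[[length(truth_windows) + 1L]] <- list(
        chrom = ch, class = cls, index = wi, start = wstart, end = wend,
        theta = theta_w, demography = sc$demography$type,
        expected_d_sign = exp_sign, hotspot = mult > 1)
      if (S == 0) next
      pos <- sort(avail[sample.int(length(avail), S)])
      gm <- sim$genotypes[, seq_len(S), drop = FALSE]

      for (s in seq_len(S)) {
        p <- pos[s]
        refb <- seq_ch[p]
        is_snp <- stats::runif(1) >= sc$indel_fraction
        indel_len <- 0L
        if (is_snp) {
          alt <- sample(setdiff(bases, refb), 1)
          ref <- refb
        } else {
          indel_len <- 1L + stats::rgeom(1, sc$indel_geom_p)
          ins <- stats::runif(1) < 0.5
          if (!ins && p + indel_len <= L &&
              !any(seq_ch[(p + 1):(p + indel_len)] == "N")) {
            ref <- paste(seq_ch[p:(p + indel_len)], collapse = "")
            alt <- refb
          } else {
            ref <- refb
            alt <- paste(c(refb, sample(bases, indel_len, replace = TRUE)),
                         collapse = "")
          }
        }
        col <- gm[, s]
        if (cls == "Y") {
          gts <- rep(".", sc$n_diploid_samples)
          gts[is_male] <- as.character(col)
        } else {
          a1 <- col[seq(1, n_chrom, by = 2)]
          a2 <- col[seq(2, n_chrom, by = 2)]
          gts <- paste0(a1, "/", a2)
        }
        an <- if (cls == "Y") sum(is_male) else n_chrom
        ac <- sum(col)
        info <- sprintf("AN=%d;AC=%d", an, ac)
        if (sc$emit_annotation) {
          ann <- .annotate_variant(p, is_snp, indel_len, genes, cds)
          info <- paste0(info, ";SO=", ann$so, ";IMPACT=", ann$impact)
          if (!is.na(ann$sift)) {
            info <- paste0(info, sprintf(";SIFT=%.4f", ann$sift))
          }
        }
        vcf_body <- c(vcf_body, paste(
          c(ch, p, ".", ref, alt, ".", "PASS", info, "GT", gts),
          collapse = "\t"))
      }
    }
    seqs[[ch]] <- paste(seq_ch, collapse = "")
  }

  fasta_path <- file.path(outdir, "reference.fa")
  dna <- Biostrings::DNAStringSet(unlist(seqs))
  names(dna) <- names(seqs)
  Biostrings::writeXStringSet(dna, fasta_path)

  gff_path <- file.path(outdir, "annotation.gff3")
  writeLines(gff_lines, gff_path)

  vcf_path <- file.path(outdir, "variants.vcf")
  hdr <- c("##fileformat=VCFv4.2",
           "##source=karyodiv_sim",
           contig_hdr,
           "##INFO=<ID=AN,Number=1,Type=Integer,Description=\"Total called alleles\">",
           "##INFO=<ID=AC,Number=A,Type=Integer,Description=\"Alt allele count\">",
           "##INFO=<ID=SO,Number=1,Type=String,Description=\"Sequence Ontology consequence\">",
           "##INFO=<ID=IMPACT,Number=1,Type=String,Description=\"Impact class\">",
           "##INFO=<ID=SIFT,Number=1,Type=Float,Description=\"SIFT score\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(hdr, vcf_body), vcf_path)

  classes_path <- file.path(outdir, "classes.tsv")
  utils::write.table(
    data.frame(chrom = names(sc$chrom_classes),
               class = unname(sc$chrom_classes)),
    classes_path, sep = "\t", quote = FALSE, row.names = FALSE)

  truth <- list(
    seed = sc$seed,
    n_diploid_samples = sc$n_diploid_samples,
    n_male = sc$n_male,
    demography = sc$demography$type,
    windows = truth_windows,
    genes = lapply(truth_genes, function(g) g[, c("start", "end", "id")]),
    gaps = truth_gaps)
  truth_path <- file.path(outdir, "truth.json")
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")

  invisible(list(fasta = fasta_path, gff3 = gff_path, vcf = vcf_path,
                 classes = classes_path, truth_path = truth_path,
                 truth = truth))
}
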