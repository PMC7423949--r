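#' Assemble a run configuration
#'
#' Collects the input paths and tunable parameters of a full analysis run.
#' Defaults are the working values used throughout the package: 100-kb
#' windows, hotspot thresholds of 10,000 SNPs / 2,000 InDels per full
#' window, a 0.5 N-fraction for the GAP label, a SIFT deleterious boundary
#' of 0.05 (inclusive), the count-ratio Ka/Ks mode and alpha = 0.05.
#'
#' @param vcf path to the multi-sample VCF.
#' @param gff character vector of GFF3 paths (merged in order).
#' @param fasta reference FASTA path.
#' @param classes path to a two-column TSV (`chrom`, `class`) or a named
#'   class-map vector.
#' @param out output directory for the report bundle.
#' @param window_size window size in bp.
#' @param snp_hotspot_threshold,indel_hotspot_threshold strict hotspot
#'   thresholds.
#' @param gap_threshold minimum N fraction for the GAP window label.
#' @param sift_threshold deleterious SIFT boundary (inclusive).
#' @param kaks_mode `"count_ratio"` or `"per_site"`.
#' @param alpha significance level for the test battery.
#' @param seed seed recorded in the manifest (the analysis itself is
#'   deterministic).
#' @return A `run_config` list.
#' @export
run_config <- function(vcf, gff, fasta, classes, out,
                       window_size = 100000L,
                       snp_hotspot_threshold = 10000L,
                       indel_hotspot_threshold = 2000L,
                       gap_threshold = 0.5,
                       sift_threshold = 0.05,
                       kaks_mode = "count_ratio",
                       alpha = 0.05,
                       seed = NA_integer_) {
  stopifnot(window_size > 0, snp_hotspot_threshold > 0,
            indel_hotspot_threshold > 0,
            alpha > 0, alpha < 1,
            gap_threshold > 0, gap_threshold <= 1)
  structure(list(vcf = vcf, gff = gff, fasta = fasta, classes = classes,
                 out = out, window_size = as.integer(window_size),
                 snp_hotspot_threshold = snp_hotspot_threshold,
                 indel_hotspot_threshold = indel_hotspot_threshold,
                 gap_threshold = gap_threshold,
                 sift_threshold = sift_threshold,
                 kaks_mode = kaks_mode, alpha = alpha, seed = seed),
            class = "run_config")
}

# Nonsynonymous / synonymous SNP counts per group from SO terms.
.kaks_counts <- function(sites, by) {
  nonsyn_terms <- c("missense_variant", "stop_gained", "stop_lost",
                    "start_lost")
  snp <- sites[!is.na(sites$vclass) & sites$vclass == "SNP" &
                 !is.na(sites$so_term), , drop = FALSE]
  grp <- unique(sites[[by]])
  out <- lapply(grp, function(g) {
    s <- snp[snp[[by]] == g, , drop = FALSE]
    data.frame(group = g,
               n_nonsyn = sum(s$so_term %in% nonsyn_terms),
               n_syn = sum(s$so_term == "synonymous_variant"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Compare chromosome classes on windowed and per-variant distributions
#'
#' The class-comparison battery: for each metric (Tajima's D and nucleotide
#' diversity across windows; InDel length and SIFT score across variants) a
#' Kruskal-Wallis test over the classes present, followed by all pairwise
#' Mann-Whitney U tests with Bonferroni correction (family size = number of
#' pairs actually run). Classes with fewer than 2 observations of a metric
#' are skipped with a message; with fewer than two usable classes the metric
#' yields no rows.
#'
#' @param wstats window-stats data.frame carrying a `class` column (join of
#'   [window_stats()] and the class map).
#' @param sites optional per-alt site data.frame (for InDel length and SIFT
#'   metrics).
#' @return data.frame of test-result rows with a `metric` column (zero rows
#'   when nothing is comparable).
#' @export
compare_classes <- function(wstats, sites = NULL) {
  metrics <- list()
  if (!is.null(wstats)) {
    metrics$tajima_d <- data.frame(value = wstats$tajima_d,
                                   class = wstats$class)
    metrics$pi <- data.frame(value = wstats$pi_std, class = wstats$class)
  }
  if (!is.null(sites)) {
    ind <- sites[!is.na(sites$vclass) & sites$vclass == "InDel", ,
                 drop = FALSE]
    if (nrow(ind) > 0) {
      metrics$indel_length <- data.frame(value = ind$indel_len,
                                         class = ind$class)
    }
    sf <- sites[!is.na(sites$sift), , drop = FALSE]
    if (nrow(sf) > 0) {
      metrics$sift <- data.frame(value = sf$sift, class = sf$class)
    }
  }
  rows <- list()
  for (mname in names(metrics)) {
    d <- metrics[[mname]]
    d <- d[!is.na(d$value) & !is.na(d$class), , drop = FALSE]
    sizes <- table(d$class)
    usable <- names(sizes)[sizes >= 2]
    if (length(usable) < 2) {
      message("metric ", mname, ": fewer than two classes with data; skipped")
      next
    }
    d <- d[d$class %in% usable, , drop = FALSE]
    kw <- kruskal_wallis(d$value, d$class)
    kw$metric <- mname
    rows[[length(rows) + 1L]] <- kw
    pairs <- utils::combn(sort(usable), 2, simplify = FALSE)
    for (pr in pairs) {
      mw <- mann_whitney_u(d$value[d$class == pr[1]],
                           d$value[d$class == pr[2]],
                           n_tests = length(pairs))
      mw$groups <- paste(pr, collapse = "|")
      mw$metric <- mname
      mw$method <- NULL
      rows[[length(rows) + 1L]] <- mw
    }
  }
  if (length(rows) == 0) {
    return(data.frame(test = character(), groups = character(),
                      statistic = numeric(), df = numeric(), n = integer(),
                      m = integer(), p_raw = numeric(),
                      p_adjusted = numeric(), correction = character(),
                      metric = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full analysis pipeline
#'
#' Reads the VCF, GFF3(s), FASTA and class map; builds the window grid from
#' the FASTA sequence lengths; computes per-window counts and
#' population-genetic statistics; classifies windows against genes and
#' assembly gaps; flags hotspots and empty windows; produces the
#' chromosome-level, InDel-length, region-density, consequence-profile and
#' class-comparison test tables; and writes everything as TSV reports plus a
#' JSON manifest (config echo, package version, input checksums). Identical
#' inputs and config give byte-identical outputs. On failure, partial
#' outputs are removed.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list of the computed tables (`window_stats`,
#'   `windows_classified`, `chromosome_summary`, `indel_lengths`,
#'   `region_density`, `impact_profile`, `test_results`) and the manifest.
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  for (p in c(config$vcf, config$gff, config$fasta)) {
    if (!file.exists(p)) stop("missing input: ", p)
  }
  if (is.character(config$classes) && length(config$classes) == 1 &&
      file.exists(config$classes)) {
    cm_df <- utils::read.delim(config$classes, stringsAsFactors = FALSE,
                               colClasses = "character")
    class_map <- chromosome_class_map(cm_df$chrom, cm_df$class)
  } else {
    class_map <- config$classes
  }
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  on_fail <- function(e) {
    unlink(written)
    stop(e)
  }
  tryCatch({
    sites <- read_vcf(config$vcf, class_map)
    genes <- read_gff_merged(config$gff, class_map)
    fa <- Biostrings::readDNAStringSet(config$fasta)
    names(fa) <- sub("\\s.*$", "", names(fa))
    lengths <- stats::setNames(Biostrings::width(fa), names(fa))
    gaps <- detect_gap_runs(fa, class_map = class_map)

    grid <- window_grid(lengths, config$window_size)
    wstats <- window_stats(sites, grid)
    wstats$class <- unname(class_map[wstats$chrom])

    wclass <- classify_windows(bin_variants(sites, grid), genes, gaps,
                               gap_threshold = config$gap_threshold)
    wclass <- find_hotspots(wclass,
                            snp_threshold = config$snp_hotspot_threshold,
                            indel_threshold = config$indel_hotspot_threshold)

    per_chrom_sites <- function(v) {
      u <- sites[!is.na(sites$vclass) & sites$vclass == v, , drop = FALSE]
      cnt <- tapply(u$site_key, u$chrom, function(x) length(unique(x)))
      out <- stats::setNames(rep(0L, length(lengths)), names(lengths))
      out[names(cnt)] <- as.integer(cnt)
      out
    }
    gene_counts <- {
      cnt <- table(genes$genes$chrom)
      out <- stats::setNames(rep(0L, length(lengths)), names(lengths))
      out[names(cnt)] <- as.integer(cnt)
      out
    }
    kk_tab <- .kaks_counts(sites, "chrom")
    kk <- stats::setNames(
      vapply(seq_len(nrow(kk_tab)), function(i) {
        as.numeric(ka_ks(kk_tab$n_nonsyn[i], kk_tab$n_syn[i],
                         mode = config$kaks_mode))
      }, 0),
      kk_tab$group)
    csum <- chromosome_summary(lengths, gene_counts,
                               per_chrom_sites("SNP"),
                               per_chrom_sites("InDel"),
                               class_map, kaks = kk)

    ilen <- indel_length_summary(sites)
    rdens <- region_density(sites, genes, lengths)
    iprof <- impact_profile(sites)
    tests <- compare_classes(wstats, sites)
    # per-chromosome density-uniformity tests join the battery
    for (ch in unique(grid$chrom)) {
      g <- wstats[wstats$chrom == ch, , drop = FALSE]
      if (nrow(g) < 2 || sum(g$n_snp) == 0) next
      ut <- uniformity_test(g$n_snp, g$width)
      ut$groups <- ch
      ut$metric <- "snp_window_counts"
      ut$note <- NULL
      tests <- rbind(tests, ut[names(tests)])
    }

    paths <- c(window_stats = "window_stats.tsv",
               windows_classified = "windows_classified.tsv",
               chromosome_summary = "chromosome_summary.tsv",
               indel_lengths = "indel_lengths.tsv",
               region_density = "region_density.tsv",
               impact_profile = "impact_profile.tsv",
               test_results = "test_results.tsv")
    tables <- list(window_stats = wstats, windows_classified = wclass,
                   chromosome_summary = csum, indel_lengths = ilen,
                   region_density = rdens, impact_profile = iprof,
                   test_results = tests)
    for (nm in names(paths)) {
      fp <- file.path(config$out, paths[[nm]])
      write_report(tables[[nm]], fp)
      written <- c(written, fp)
    }
    manifest <- list(
      package = "karyodiv",
      version = as.character(utils::packageVersion("karyodiv")),
      seed = config$seed,
      window_size = config$window_size,
      snp_hotspot_threshold = config$snp_hotspot_threshold,
      indel_hotspot_threshold = config$indel_hotspot_threshold,
      gap_threshold = config$gap_threshold,
      sift_threshold = config$sift_threshold,
      kaks_mode = config$kaks_mode,
      alpha = config$alpha,
      inputs = lapply(
        stats::setNames(c(config$vcf, config$gff, config$fasta),
                        c("vcf", paste0("gff", seq_along(config$gff)),
                          "fasta")),
        function(p) list(path = p, md5 = unname(tools::md5sum(p)))),
      n_symbolic_rejected = attr(sites, "n_symbolic_rejected"))
    mf <- file.path(config$out, "manifest.json")
    jsonlite::write_json(manifest, mf, auto_unbox = TRUE, pretty = TRUE)
    written <- c(written, mf)
    tables$manifest <- manifest
    invisible(tables)
  }, error = on_fail)
}
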