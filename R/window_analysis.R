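#' Fixed non-overlapping window grid
#'
#' Tiles each chromosome with windows of `window_size` bp, 1-based closed
#' (`[1, 100000]`, `[100001, 200000]`, ...); the last window is truncated at
#' the chromosome end so window lengths sum exactly to the chromosome length.
#'
#' @param chrom_lengths named numeric vector of chromosome lengths in bp.
#' @param window_size window size in bp (default 100,000).
#' @return data.frame `chrom`, `start`, `end`, `width`, `index` (per-chrom
#'   window number), `truncated`; attribute `window_size`.
#' @export
window_grid <- function(chrom_lengths, window_size = 100000L) {
  stopifnot(window_size > 0, length(chrom_lengths) > 0,
            !is.null(names(chrom_lengths)))
  out <- lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    if (len <= 0) stop("non-positive length for chromosome ", ch)
    starts <- seq.int(1L, len, by = window_size)
    ends <- pmin(starts + window_size - 1L, len)
    data.frame(chrom = ch, start = as.integer(starts), end = as.integer(ends),
               width = as.integer(ends - starts + 1L),
               index = seq_along(starts),
               truncated = ends - starts + 1L < window_size,
               stringsAsFactors = FALSE)
  })
  grid <- do.call(rbind, out)
  rownames(grid) <- NULL
  attr(grid, "window_size") <- as.integer(window_size)
  grid
}

# Row index of `grid` for every site row; errors if a site lies beyond the
# chromosome end; NA for chromosomes absent from the grid.
.assign_windows <- function(sites, grid) {
  if (is.null(sites) || nrow(sites) == 0) return(integer(0))
  wsize <- attr(grid, "window_size")
  key <- paste0(grid$chrom, ":", grid$index)
  lookup <- stats::setNames(seq_len(nrow(grid)), key)
  widx <- (sites$pos - 1L) %/% wsize + 1L
  skey <- paste0(sites$chrom, ":", widx)
  row <- unname(lookup[skey])
  chrom_end <- tapply(grid$end, grid$chrom, max)
  over <- sites$chrom %in% names(chrom_end) &
    sites$pos > chrom_end[sites$chrom]
  if (any(over)) {
    i <- which(over)[1]
    stop("site ", sites$chrom[i], ":", sites$pos[i],
         " lies beyond the chromosome end")
  }
  row
}

#' Bin variants into windows
#'
#' Counts SNPs and InDels per window. Each variant site is assigned to
#' exactly one window by its POS (the anchor base for InDels); a multiallelic
#' site counts once per variant class it carries (once for density even with
#' several alternate alleles of the same class).
#'
#' @param sites per-alt site data.frame from [read_vcf()].
#' @param grid window grid from [window_grid()].
#' @return The grid with `n_snp` and `n_indel` columns appended.
#' @export
bin_variants <- function(sites, grid) {
  out <- grid
  out$n_snp <- 0L
  out$n_indel <- 0L
  if (is.null(sites) || nrow(sites) == 0) return(out)
  ord <- order(sites$chrom, sites$pos)
  sites <- sites[ord, , drop = FALSE]
  row <- .assign_windows(sites, grid)
  ok <- !is.na(row) & !is.na(sites$vclass)
  if (!any(ok)) return(out)
  s <- sites[ok, , drop = FALSE]
  r <- row[ok]
  # one count per (window, site, class)
  key_snp <- unique(paste0(r, "|", s$site_key)[s$vclass == "SNP"])
  key_ind <- unique(paste0(r, "|", s$site_key)[s$vclass == "InDel"])
  tab_from <- function(keys) {
    w <- as.integer(sub("\\|.*$", "", keys))
    tabulate(w, nbins = nrow(grid))
  }
  out$n_snp <- tab_from(key_snp)
  out$n_indel <- tab_from(key_ind)
  out
}

#' Chi-square test of uniform variant density across windows
#'
#' Goodness-of-fit test of the observed per-window counts against equal
#' density per bp: the expected count of window i is
#' `total * width_i / sum(width)`, so a truncated final window gets a
#' length-scaled expectation.
#'
#' @param counts integer vector of per-window variant counts (>= 2 windows).
#' @param widths window lengths in bp; equal lengths assumed when omitted.
#' @return A one-row test-result data.frame (see [chi2_gof()]); when all
#'   counts are zero the test is undefined and statistic and p are `NA` with
#'   `note = "undefined"`.
#' @export
uniformity_test <- function(counts, widths = NULL) {
  k <- length(counts)
  if (k < 2) stop("need at least 2 windows")
  if (is.null(widths)) widths <- rep(1, k)
  stopifnot(length(widths) == k, all(widths > 0))
  total <- sum(counts)
  if (total == 0) {
    res <- .test_result("chi2_gof_uniformity", groups = "windows",
                        statistic = NA_real_, df = k - 1, p_raw = NA_real_)
    res$note <- "undefined"
    return(res)
  }
  expected <- total * widths / sum(widths)
  res <- chi2_gof(counts, expected)
  res$test <- "chi2_gof_uniformity"
  res
}

#' Classify windows against genes and assembly gaps
#'
#' For every window computes the fraction of its length covered by gene
#' spans (not CDS) and by reference N runs, then labels it: `GAP` when
#' `gap_frac >= gap_threshold`, otherwise `INTERGENIC` when it overlaps no
#' gene, otherwise `GENIC`. The three labels partition the grid.
#'
#' @param grid window grid (optionally already carrying counts).
#' @param genes GeneSet list from [read_gff_merged()] (uses `$genes`), or a
#'   data.frame with `chrom`, `start`, `end`.
#' @param gaps gap-run data.frame from [detect_gap_runs()].
#' @param gap_threshold minimum N fraction for the `GAP` label (default 0.5:
#'   a gap window is mostly Ns).
#' @return The grid with `gene_overlap_frac`, `gap_frac`, `label` appended.
#' @export
classify_windows <- function(grid, genes, gaps = NULL, gap_threshold = 0.5) {
  gdf <- if (is.list(genes) && !is.data.frame(genes)) genes$genes else genes
  out <- grid
  out$gene_overlap_frac <- 0
  out$gap_frac <- 0
  frac_covered <- function(intervals) {
    frac <- numeric(nrow(grid))
    if (is.null(intervals) || nrow(intervals) == 0) return(frac)
    for (ch in unique(grid$chrom)) {
      gi <- grid$chrom == ch
      ii <- intervals$chrom == ch
      if (!any(ii)) next
      red <- IRanges::reduce(IRanges::IRanges(intervals$start[ii],
                                              intervals$end[ii]))
      win <- IRanges::IRanges(grid$start[gi], grid$end[gi])
      ov <- IRanges::findOverlaps(win, red)
      if (length(ov) == 0) next
      inter <- IRanges::pintersect(win[S4Vectors::queryHits(ov)],
                                   red[S4Vectors::subjectHits(ov)])
      cov_bp <- tapply(IRanges::width(inter), S4Vectors::queryHits(ov), sum)
      f <- numeric(sum(gi))
      f[as.integer(names(cov_bp))] <- cov_bp
      frac[gi] <- f / IRanges::width(win)
    }
    frac
  }
  out$gene_overlap_frac <- frac_covered(gdf)
  out$gap_frac <- frac_covered(gaps)
  out$label <- ifelse(out$gap_frac >= gap_threshold, "GAP",
                      ifelse(out$gene_overlap_frac == 0, "INTERGENIC",
                             "GENIC"))
  out
}

#' Flag variant-density hotspots
#'
#' Windows whose SNP or InDel count strictly exceeds the threshold are
#' flagged. Defaults follow the working definition of a hotspot in a 100-kb
#' window: more than 10,000 SNPs or more than 2,000 InDels. Truncated final
#' windows are excluded (a shorter window cannot be compared against a
#' full-window threshold).
#'
#' @param counts grid with `n_snp`/`n_indel` (from [bin_variants()] or
#'   [window_stats()]), optionally with classification columns.
#' @param snp_threshold,indel_threshold strict thresholds (> 0).
#' @param exclude_truncated drop truncated windows from flagging.
#' @return The input with logical `hotspot_snp`, `hotspot_indel` columns.
#' @export
find_hotspots <- function(counts, snp_threshold = 10000L,
                          indel_threshold = 2000L,
                          exclude_truncated = TRUE) {
  stopifnot(snp_threshold > 0, indel_threshold > 0)
  out <- counts
  eligible <- if (exclude_truncated && "truncated" %in% names(out)) {
    !out$truncated
  } else rep(TRUE, nrow(out))
  out$hotspot_snp <- eligible & out$n_snp > snp_threshold
  out$hotspot_indel <- eligible & out$n_indel > indel_threshold
  out
}

#' List empty windows, partitioned by classification
#'
#' Windows with zero variants of the requested class, labelled
#' GAP/INTERGENIC/GENIC so that summaries of the form "k of the n empty
#' windows correspond to assembly gaps" can be produced.
#'
#' @param classified grid with counts and a `label` column (from
#'   [classify_windows()] after [bin_variants()]).
#' @param type `"snp"` or `"indel"`.
#' @return Subset of the classified grid with zero counts of the given type.
#' @export
find_empty_windows <- function(classified, type = c("snp", "indel")) {
  type <- match.arg(type)
  col <- if (type == "snp") "n_snp" else "n_indel"
  stopifnot(col %in% names(classified), "label" %in% names(classified))
  out <- classified[classified[[col]] == 0L, , drop = FALSE]
  rownames(out) <- NULL
  out
}
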