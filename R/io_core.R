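#' Build a chromosome class map
#'
#' Assigns each chromosome to one of the three comparison groups used
#' throughout the package: autosomes, the X chromosome and the Y chromosome.
#'
#' @param chroms character vector of chromosome identifiers.
#' @param classes character vector of the same length with values
#'   `"AUTOSOME"`, `"X"` or `"Y"`.
#' @return A named character vector mapping chromosome id to class.
#' @export
#' @examples
#' chromosome_class_map(c("1", "2", "X", "Y"),
#'                      c("AUTOSOME", "AUTOSOME", "X", "Y"))
chromosome_class_map <- function(chroms, classes) {
  stopifnot(length(chroms) == length(classes))
  classes <- toupper(classes)
  bad <- setdiff(unique(classes), c("AUTOSOME", "X", "Y"))
  if (length(bad) > 0) {
    stop("unknown chromosome class(es): ", paste(bad, collapse = ", "))
  }
  if (anyDuplicated(chroms)) {
    stop("duplicated chromosome id in class map")
  }
  stats::setNames(classes, as.character(chroms))
}

.check_chroms_in_map <- function(chroms, class_map, what = "input") {
  missing <- setdiff(unique(as.character(chroms)), names(class_map))
  if (length(missing) > 0) {
    stop(what, " contains chromosome(s) absent from the class map: ",
         paste(missing, collapse = ", "))
  }
  invisible(TRUE)
}

#' Classify a variant as SNP or InDel
#'
#' A site is a SNP when both REF and ALT are single bases; otherwise it is an
#' InDel whose length is the absolute difference of allele lengths. Symbolic
#' alleles (e.g. `<DEL>`, breakends) cannot be classified and are returned as
#' `NA` with a warning counting the rejections.
#'
#' @param ref character vector of reference alleles.
#' @param alt character vector of alternate alleles (same length).
#' @return A data.frame with columns `vclass` (`"SNP"`/`"InDel"`/`NA`) and
#'   `indel_len` (0 for SNPs).
#' @export
#' @examples
#' classify_variant("A", "G")      # SNP
#' classify_variant("ACGT", "A")   # 3-bp deletion
classify_variant <- function(ref, alt) {
  stopifnot(length(ref) == length(alt))
  if (any(!nzchar(ref)) || any(!nzchar(alt))) {
    stop("empty allele string")
  }
  symbolic <- grepl("<|>|\\[|\\]", alt) | alt == "*" |
    grepl("<|>|\\[|\\]", ref)
  lr <- nchar(ref)
  la <- nchar(alt)
  vclass <- ifelse(lr == 1L & la == 1L, "SNP", "InDel")
  indel_len <- ifelse(vclass == "InDel", abs(lr - la), 0L)
  vclass[symbolic] <- NA_character_
  indel_len[symbolic] <- NA_integer_
  n_sym <- sum(symbolic)
  if (n_sym > 0) {
    warning(n_sym, " symbolic allele(s) rejected")
  }
  out <- data.frame(vclass = vclass, indel_len = as.integer(indel_len),
                    stringsAsFactors = FALSE)
  attr(out, "n_symbolic_rejected") <- n_sym
  out
}

# Parse a single INFO key (KEY=value) out of VCF INFO strings; NA when absent.
.info_field <- function(info, key) {
  pat <- paste0("(?:^|;)", key, "=([^;]+)")
  m <- regmatches(info, regexec(pat, info))
  vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_, "")
}

#' Read a multi-sample VCF into per-alt site records
#'
#' Reads a VCF (plain or bgzipped) with vcfR and recomputes AN (total called
#' alleles) and per-alt AC directly from the GT fields: missing genotypes
#' reduce AN and are never imputed, and haploid calls (e.g. hemizygous Y in
#' males) contribute a single allele. Multiallelic sites yield one row per
#' alternate allele sharing a `site_key`; each alt is classified SNP/InDel
#' independently. The optional INFO keys `SO` (Sequence Ontology consequence
#' term), `IMPACT` and `SIFT` are carried through when present.
#'
#' @param path VCF file path.
#' @param class_map named character vector from [chromosome_class_map()];
#'   every VCF chromosome must be present.
#' @return A data.frame with one row per (site, alt): `chrom`, `pos`,
#'   `site_key`, `ref`, `alt`, `an`, `ac`, `vclass`, `indel_len`, `so_term`,
#'   `impact`, `sift`, `class`. Rows with symbolic alleles are dropped
#'   (counted in attribute `n_symbolic_rejected`).
#' @export
read_vcf <- function(path, class_map) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf, getINFO = TRUE)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  chrom <- as.character(fix[, "CHROM"])
  .check_chroms_in_map(chrom, class_map, "VCF")
  pos <- as.integer(fix[, "POS"])
  if (any(is.na(pos)) || any(pos < 1)) {
    bad <- which(is.na(pos) | pos < 1)[1]
    stop("malformed VCF record at data line ", bad, ": bad POS")
  }
  ref <- as.character(fix[, "REF"])
  alt <- as.character(fix[, "ALT"])
  if (any(is.na(ref)) || any(is.na(alt))) {
    bad <- which(is.na(ref) | is.na(alt))[1]
    stop("malformed VCF record at data line ", bad, ": missing allele")
  }
  info <- as.character(fix[, "INFO"])

  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = length(chrom))

  n_sites <- length(chrom)
  alt_list <- strsplit(alt, ",", fixed = TRUE)
  so <- .info_field(info, "SO")
  imp <- .info_field(info, "IMPACT")
  sift <- suppressWarnings(as.numeric(.info_field(info, "SIFT")))

  rows <- vector("list", n_sites)
  for (i in seq_len(n_sites)) {
    calls <- gt[i, ]
    toks <- unlist(strsplit(calls[!is.na(calls)], "[/|]"))
    toks <- toks[toks != "." & nzchar(toks)]
    an <- length(toks)
    alts_i <- alt_list[[i]]
    ac <- vapply(seq_along(alts_i),
                 function(j) sum(toks == as.character(j)), 0L)
    rows[[i]] <- data.frame(
      chrom = chrom[i], pos = pos[i],
      site_key = paste0(chrom[i], ":", pos[i]),
      ref = ref[i], alt = alts_i, an = an, ac = ac,
      so_term = so[i], impact = imp[i], sift = sift[i],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  cls <- withCallingHandlers(
    classify_variant(out$ref, out$alt),
    warning = function(w) invokeRestart("muffleWarning"))
  out$vclass <- cls$vclass
  out$indel_len <- cls$indel_len
  n_sym <- attr(cls, "n_symbolic_rejected")
  out <- out[!is.na(out$vclass), , drop = FALSE]
  out$class <- unname(class_map[out$chrom])
  rownames(out) <- NULL
  attr(out, "n_symbolic_rejected") <- n_sym
  out
}

# Pick a stable feature identifier from GFF3 metadata columns.
.gff_id <- function(mcols_df, fallback_prefix) {
  for (key in c("ID", "Name", "gene_id", "gene")) {
    if (key %in% names(mcols_df)) {
      v <- as.character(mcols_df[[key]])
      if (!all(is.na(v))) return(v)
    }
  }
  paste0(fallback_prefix, seq_len(nrow(mcols_df)))
}

#' Read and merge one or more GFF3 annotation files
#'
#' Imports each GFF3 with rtracklayer, keeps `gene` and `CDS` features, and
#' merges across files. Entries identical in (chrom, start, end, id) are
#' deduplicated; a gene id reappearing with different coordinates is kept from
#' the earlier file and the collision is reported via `message()` rather than
#' silently overwritten.
#'
#' @param paths character vector of GFF3 paths, in priority order.
#' @param class_map optional class map; when given, chromosomes are validated
#'   against it.
#' @return A list with data.frames `genes` (`chrom`, `start`, `end`,
#'   `strand`, `id`) and `cds` (`chrom`, `start`, `end`, `strand`, `phase`,
#'   `gene_id`), 1-based closed coordinates.
#' @export
read_gff_merged <- function(paths, class_map = NULL) {
  gene_tabs <- list()
  cds_tabs <- list()
  for (p in paths) {
    if (!file.exists(p)) stop("GFF3 not found: ", p)
    gr <- rtracklayer::import(p, format = "gff3")
    if (any(BiocGenerics::end(gr) < BiocGenerics::start(gr))) {
      stop("GFF3 feature with end < start in ", p)
    }
    md <- as.data.frame(S4Vectors::mcols(gr))
    type <- as.character(md$type)
    g <- gr[type == "gene"]
    if (length(g) > 0) {
      gmd <- as.data.frame(S4Vectors::mcols(g))
      gene_tabs[[length(gene_tabs) + 1L]] <- data.frame(
        chrom = as.character(GenomicRanges::seqnames(g)),
        start = BiocGenerics::start(g), end = BiocGenerics::end(g),
        strand = as.character(BiocGenerics::strand(g)),
        id = .gff_id(gmd, "gene"),
        stringsAsFactors = FALSE)
    }
    cc <- gr[type == "CDS"]
    if (length(cc) > 0) {
      cmd <- as.data.frame(S4Vectors::mcols(cc))
      parent <- if ("Parent" %in% names(cmd)) {
        vapply(cmd$Parent, function(x) {
          if (length(x) > 0) as.character(x[[1]]) else NA_character_
        }, "")
      } else {
        .gff_id(cmd, "cds")
      }
      phase <- if ("phase" %in% names(cmd)) as.integer(cmd$phase) else 0L
      cds_tabs[[length(cds_tabs) + 1L]] <- data.frame(
        chrom = as.character(GenomicRanges::seqnames(cc)),
        start = BiocGenerics::start(cc), end = BiocGenerics::end(cc),
        strand = as.character(BiocGenerics::strand(cc)),
        phase = phase, gene_id = parent,
        stringsAsFactors = FALSE)
    }
  }
  genes <- if (length(gene_tabs) > 0) do.call(rbind, gene_tabs) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               strand = character(), id = character())
  cds <- if (length(cds_tabs) > 0) do.call(rbind, cds_tabs) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               strand = character(), phase = integer(), gene_id = character())

  # exact duplicates collapse; same id at different coords: keep first, log
  if (nrow(genes) > 0) {
    key_full <- paste(genes$chrom, genes$start, genes$end, genes$id)
    genes <- genes[!duplicated(key_full), , drop = FALSE]
    dup_id <- duplicated(genes$id)
    if (any(dup_id)) {
      message("gene id collision(s) with differing coordinates: ",
              paste(unique(genes$id[dup_id]), collapse = ", "),
              " (keeping first occurrence)")
      genes <- genes[!dup_id, , drop = FALSE]
    }
  }
  if (nrow(cds) > 0) {
    keyc <- paste(cds$chrom, cds$start, cds$end, cds$gene_id)
    cds <- cds[!duplicated(keyc), , drop = FALSE]
  }
  rownames(genes) <- NULL
  rownames(cds) <- NULL
  if (!is.null(class_map) && nrow(genes) > 0) {
    .check_chroms_in_map(genes$chrom, class_map, "GFF3")
  }
  list(genes = genes, cds = cds)
}

#' Detect assembly gaps (N runs) in a reference FASTA
#'
#' Finds maximal runs of `N`/`n` bases per sequence; runs shorter than
#' `min_gap_run` are ignored.
#'
#' @param fasta path to a FASTA file or a `Biostrings::DNAStringSet`.
#' @param min_gap_run minimum run length to report (default 1).
#' @param class_map optional class map; chromosomes listed there must be
#'   present in the FASTA.
#' @return A data.frame `chrom`, `start`, `end` of 1-based closed N runs,
#'   sorted and non-overlapping.
#' @export
detect_gap_runs <- function(fasta, min_gap_run = 1L, class_map = NULL) {
  seqs <- if (inherits(fasta, "DNAStringSet")) fasta else
    Biostrings::readDNAStringSet(fasta)
  nm <- sub("\\s.*$", "", names(seqs))
  if (!is.null(class_map)) {
    absent <- setdiff(names(class_map), nm)
    if (length(absent) > 0) {
      stop("chromosome(s) in class map missing from FASTA: ",
           paste(absent, collapse = ", "))
    }
  }
  out <- list()
  for (i in seq_along(seqs)) {
    s <- as.character(seqs[[i]])
    m <- gregexpr("[Nn]+", s)[[1]]
    if (m[1] == -1) next
    start <- as.integer(m)
    len <- attr(m, "match.length")
    keep <- len >= min_gap_run
    if (!any(keep)) next
    out[[length(out) + 1L]] <- data.frame(
      chrom = nm[i], start = start[keep],
      end = start[keep] + len[keep] - 1L, stringsAsFactors = FALSE)
  }
  if (length(out) == 0) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Write / read a tabular report with lossless numeric round-trip
#'
#' TSV writer/reader pair used for all pipeline outputs. Doubles are written
#' with 17 significant digits so that re-reading reproduces them bit-exactly.
#'
#' @param df data.frame to write.
#' @param path output TSV path.
#' @return `write_report` returns `path` invisibly; `read_report` returns the
#'   data.frame.
#' @export
write_report <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      v <- out[[j]]
      s <- sprintf("%.17g", v)
      s[is.na(v)] <- NA_character_
      out[[j]] <- s
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    na.strings = "NA")
}
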