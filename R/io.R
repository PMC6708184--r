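#' Reference target sequences
#'
#' A set of named DNA sequences (amplicon or capture targets). Stored as a
#' named uppercase character vector; the names are the target identifiers
#' used in all coordinates (1-based, as in VCF/GFF3).
#'
#' @param sequences named character vector of DNA sequences.
#' @return named uppercase character vector, validated.
#' @export
reference_targets <- function(sequences) {
  if (is.null(names(sequences)) || any(!nzchar(names(sequences)))) {
    .stopf("every target sequence must be named")
  }
  if (anyDuplicated(names(sequences))) {
    .stopf("duplicate target names: %s",
           paste(unique(names(sequences)[duplicated(names(sequences))]),
                 collapse = ", "))
  }
  sequences <- toupper(sequences)
  bad <- grepl("[^ACGTN]", sequences)
  if (any(bad)) {
    .stopf("target '%s' contains non-ACGTN characters",
           names(sequences)[bad][1])
  }
  if (any(!nzchar(sequences))) {
    .stopf("target '%s' has an empty sequence",
           names(sequences)[!nzchar(sequences)][1])
  }
  sequences
}

#' Read reference targets from a FASTA file
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()] with a line-level
#' pre-check so that malformed records are reported with the offending line
#' number. Sequences are uppercased; record order is preserved.
#'
#' @param path FASTA file.
#' @return named character vector of uppercase sequences (see
#'   [reference_targets()]).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) .stopf("no such file: %s", path)
  lines <- readLines(path)
  hdr <- grep("^>", lines)
  if (length(hdr) == 0L) .stopf("%s: no FASTA header found (line 1)", path)
  if (hdr[1] != 1L && any(nzchar(trimws(lines[seq_len(hdr[1] - 1L)])))) {
    .stopf("%s: sequence data before first header (line 1)", path)
  }
  ends <- c(hdr[-1] - 1L, length(lines))
  for (i in seq_along(hdr)) {
    body_ln <- setdiff(seq(hdr[i], ends[i]), hdr[i])
    body <- lines[body_ln]
    if (!any(nzchar(trimws(body)))) {
      .stopf("%s: empty sequence for record '%s' (line %d)",
             path, sub("^>\\s*", "", lines[hdr[i]]), hdr[i])
    }
    bad <- grepl("[^ACGTNacgtn[:space:]]", body)
    if (any(bad)) {
      .stopf("%s: non-ACGTN characters in record '%s' (line %d)",
             path, sub("^>\\s*", "", lines[hdr[i]]), body_ln[bad][1])
    }
  }
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(ss))
  reference_targets(seqs)
}

#' Write reference targets to a FASTA file
#'
#' @param targets named character vector of sequences.
#' @param path output file.
#' @param width line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(targets, path, width = 70L) {
  ss <- Biostrings::DNAStringSet(targets)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Read a pool sample sheet
#'
#' The sample sheet maps sequencing libraries to the pooling design: one
#' row per pool with columns `pool_id`, `block`, `axis` (`row` or
#' `column`) and `index` (the 1-based row or column number).
#'
#' @param path TSV file with the four-column header above.
#' @return validated data frame.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) .stopf("no such file: %s", path)
  sheet <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("pool_id", "block", "axis", "index")
  miss <- setdiff(need, names(sheet))
  if (length(miss)) {
    .stopf("sample sheet %s is missing column(s): %s", path,
           paste(miss, collapse = ", "))
  }
  sheet <- sheet[need]
  bad_axis <- !sheet$axis %in% c("row", "column")
  if (any(bad_axis)) {
    .stopf("row %d: axis '%s' invalid (allowed values: row, column)",
           which(bad_axis)[1], sheet$axis[bad_axis][1])
  }
  if (any(sheet$block < 1L) || any(sheet$index < 1L)) {
    .stopf("row %d: block and index must be >= 1",
           which(sheet$block < 1L | sheet$index < 1L)[1])
  }
  key <- paste(sheet$block, sheet$axis, sheet$index)
  if (anyDuplicated(key)) {
    d <- which(duplicated(key))[1]
    .stopf("row %d: duplicate pool position (block %s, %s, index %s)",
           d, sheet$block[d], sheet$axis[d], sheet$index[d])
  }
  if (anyDuplicated(sheet$pool_id)) {
    .stopf("duplicate pool_id: %s",
           sheet$pool_id[duplicated(sheet$pool_id)][1])
  }
  sheet
}

#' Write a sample sheet
#'
#' @param sheet data frame as returned by [layout_sample_sheet()] or
#'   [read_sample_sheet()].
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(sheet, path) {
  write.table(sheet, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read variant records from a VCF file
#'
#' Parses a VCF 4.x file (via \pkg{vcfR}) into the flat per-sample record
#' layout used throughout the package: one row per (site, alternate
#' allele, sample). Multi-allelic sites are decomposed into biallelic
#' records sharing the position. Depth and alternate read counts are taken
#' from the per-sample `AD` field when present, falling back to `DP` for
#' depth; a record carrying neither is an error. `QD`, `FS` and `SOR` are
#' lifted from INFO when present (NA otherwise).
#'
#' @param path VCF file (plain or gzipped).
#' @param keep_missing keep sample entries with missing genotype data
#'   (`FALSE` by default: rows where both AD and DP are missing for that
#'   sample are dropped rather than an error, provided the site has the
#'   fields defined).
#' @return data frame with columns target, position, ref, alt, sample_id,
#'   depth, alt_count, gt, QD, FS, SOR.
#' @export
read_vcf <- function(path, keep_missing = FALSE) {
  if (!file.exists(path)) .stopf("no such file: %s", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fixm <- vcfR::getFIX(v)
  if (is.null(dim(fixm))) fixm <- t(fixm)  # single-record VCF
  fix <- as.data.frame(fixm, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) {
    return(.empty_variant_records())
  }
  fmt <- unique(v@gt[, "FORMAT"])
  has_ad <- any(grepl("\\bAD\\b", fmt))
  has_dp <- any(grepl("\\bDP\\b", fmt))
  if (!has_ad && !has_dp) {
    .stopf("%s: FORMAT defines neither AD nor DP; per-sample depths required",
           path)
  }
  ad <- if (has_ad) vcfR::extract.gt(v, "AD") else NULL
  dp <- if (has_dp) suppressWarnings(vcfR::extract.gt(v, "DP", as.numeric = TRUE)) else NULL
  gt <- tryCatch(vcfR::extract.gt(v, "GT"), error = function(e) NULL)
  samples <- colnames(v@gt)[-1]
  info_num <- function(key) {
    suppressWarnings(as.numeric(vcfR::extract.info(v, key)))
  }
  qd <- info_num("QD"); fs <- info_num("FS"); sor <- info_num("SOR")

  out <- vector("list", nrow(fix))
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    ads <- if (!is.null(ad)) {
      lapply(ad[i, ], function(x) {
        if (is.na(x)) return(NA_real_)
        suppressWarnings(as.numeric(strsplit(x, ",", fixed = TRUE)[[1]]))
      })
    } else NULL
    for (k in seq_along(alts)) {
      depth <- alt_count <- rep(NA_real_, length(samples))
      for (s in seq_along(samples)) {
        a <- if (!is.null(ads)) ads[[s]] else NA_real_
        if (length(a) > 1L && !anyNA(a)) {
          depth[s] <- sum(a)
          alt_count[s] <- a[k + 1L]
        } else if (!is.null(dp) && !is.na(dp[i, s])) {
          depth[s] <- dp[i, s]
        }
      }
      keep <- if (keep_missing) rep(TRUE, length(samples)) else !is.na(depth)
      if (!any(keep)) {
        .stopf("%s: record %s:%s has no usable AD/DP for any sample",
               path, fix$CHROM[i], fix$POS[i])
      }
      out[[length(out) + 1L]] <- data.frame(
        target = fix$CHROM[i], position = as.integer(fix$POS[i]),
        ref = fix$REF[i], alt = alts[k],
        sample_id = samples[keep],
        depth = depth[keep],
        alt_count = ifelse(is.na(alt_count[keep]), 0, alt_count[keep]),
        gt = if (!is.null(gt)) gt[i, samples[keep]] else NA_character_,
        QD = qd[i], FS = fs[i], SOR = sor[i],
        stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  rownames(res) <- NULL
  res
}

#' @noRd
.empty_variant_records <- function() {
  data.frame(target = character(), position = integer(), ref = character(),
             alt = character(), sample_id = character(), depth = numeric(),
             alt_count = numeric(), gt = character(), QD = numeric(),
             FS = numeric(), SOR = numeric(), stringsAsFactors = FALSE)
}

#' Write variant records to a VCF file
#'
#' Inverse of [read_vcf()] for the fields this package uses. Each
#' decomposed (site, alternate) record becomes one VCF line; samples are
#' emitted as `GT:DP:AD` columns. INFO carries QD/FS/SOR when present plus
#' any extra `info` strings supplied per record.
#'
#' @param records data frame in the [read_vcf()] layout (`gt`, `QD`, `FS`,
#'   `SOR` optional).
#' @param path output file.
#' @param info optional character vector, one extra INFO string per
#'   distinct VCF line (recycled if length 1).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(records, path, info = NULL) {
  samples <- sort(unique(records$sample_id))
  key <- paste(records$target, records$position, records$ref, records$alt)
  sites <- records[!duplicated(key), c("target", "position", "ref", "alt"),
                   drop = FALSE]
  ord <- order(sites$target, sites$position, sites$alt)
  sites <- sites[ord, , drop = FALSE]
  skey <- paste(sites$target, sites$position, sites$ref, sites$alt)
  if (!is.null(info)) info <- rep_len(info, nrow(sites))

  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=gridtill",
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Quality by depth\">",
    "##INFO=<ID=FS,Number=1,Type=Float,Description=\"Fisher strand bias\">",
    "##INFO=<ID=SOR,Number=1,Type=Float,Description=\"Strand odds ratio\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  ), con)
  for (i in seq_len(nrow(sites))) {
    rows <- records[key == skey[i], , drop = FALSE]
    ifields <- character(0)
    for (k in c("QD", "FS", "SOR")) {
      if (k %in% names(rows) && !is.na(rows[[k]][1])) {
        ifields <- c(ifields, sprintf("%s=%g", k, rows[[k]][1]))
      }
    }
    if (!is.null(info) && nzchar(info[i])) ifields <- c(ifields, info[i])
    istr <- if (length(ifields)) paste(ifields, collapse = ";") else "."
    cells <- vapply(samples, function(s) {
      r <- rows[rows$sample_id == s, , drop = FALSE]
      if (nrow(r) == 0L) return("./.:.:.")
      g <- if ("gt" %in% names(r) && !is.na(r$gt[1])) r$gt[1] else "./."
      sprintf("%s:%d:%d,%d", g, as.integer(r$depth[1]),
              as.integer(r$depth[1] - r$alt_count[1]),
              as.integer(r$alt_count[1]))
    }, character(1))
    writeLines(paste(c(sites$target[i], sites$position[i], ".",
                       sites$ref[i], sites$alt[i], ".", ".", istr,
                       "GT:DP:AD", cells), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Imports gene/exon/CDS features (via \pkg{rtracklayer}) and assembles one
#' [gene_model()] per gene. Exons and CDS intervals are grouped by their
#' `Parent`/`ID` attributes; a transcript level between gene and exon is
#' tolerated.
#'
#' @param path GFF3 file.
#' @param flank_bp up/downstream window passed to [gene_model()].
#' @return named list of `gene_model` objects.
#' @export
read_gene_models <- function(path, flank_bp = 5000L) {
  gr <- rtracklayer::import(path)
  df <- as.data.frame(gr)
  df$type <- as.character(df$type)
  parent_of <- function(row) {
    p <- df$Parent[[row]]
    if (length(p) == 0L) NA_character_ else as.character(p[1])
  }
  df$parent <- vapply(seq_len(nrow(df)), parent_of, character(1))
  genes <- df[df$type == "gene", , drop = FALSE]
  if (nrow(genes) == 0L) .stopf("%s: no gene features found", path)
  # map any feature to its gene through at most one transcript level
  id2gene <- setNames(as.character(genes$ID), as.character(genes$ID))
  tx <- df[!is.na(df$parent) & df$parent %in% names(id2gene) &
             !df$type %in% c("exon", "CDS"), , drop = FALSE]
  if (nrow(tx)) id2gene[as.character(tx$ID)] <- id2gene[tx$parent]
  models <- list()
  for (i in seq_len(nrow(genes))) {
    gid <- as.character(genes$ID[i])
    feat_ids <- names(id2gene)[id2gene == gid]
    sub <- df[!is.na(df$parent) & df$parent %in% feat_ids, , drop = FALSE]
    ex <- sub[sub$type == "exon", , drop = FALSE]
    cd <- sub[sub$type == "CDS", , drop = FALSE]
    if (nrow(ex) == 0L) ex <- genes[i, , drop = FALSE]
    models[[gid]] <- gene_model(
      gene_id = gid,
      target = as.character(genes$seqnames[i]),
      strand = as.character(genes$strand[i]),
      exons = cbind(start = ex$start, end = ex$end),
      cds = if (nrow(cd)) cbind(start = cd$start, end = cd$end) else NULL,
      flank_bp = flank_bp
    )
  }
  models
}
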