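#' Pooled detection thresholds
#'
#' The relaxed pooled-calling settings: a candidate needs at least
#' `min_alt_total` alternate reads and an alternate fraction of at least
#' `min_alt_fraction` (both with `>=` semantics). The default fraction,
#' 0.02, accepts one heterozygous chromosome in 50 against the 1-in-32
#' expected for a 16-plant pool; for other pool sizes the same 2/3 safety
#' margin is kept, `(2/3) / (2 * pool_size)`.
#'
#' @param min_alt_fraction minimum alternate allele fraction; default
#'   [default_min_alt_fraction()] of `pool_size`.
#' @param min_alt_total minimum alternate read count (default 30).
#' @param min_pool_depth minimum total reads for a library to be
#'   considered successful (default 1000); hits in pools below this are
#'   suppressed.
#' @param ems_only if TRUE, [detect_pool_variants()] keeps only the
#'   EMS-expected G→A / C→T changes (see [apply_ems_filter()]).
#' @param pool_size plants per pool, used only for the default fraction.
#' @return object of class `detection_params`.
#' @export
detection_params <- function(min_alt_fraction = default_min_alt_fraction(pool_size),
                             min_alt_total = 30,
                             min_pool_depth = 1000,
                             ems_only = FALSE,
                             pool_size = 16) {
  stopifnot(min_alt_fraction > 0, min_alt_fraction < 1, min_alt_total >= 1,
            min_pool_depth >= 0)
  structure(list(min_alt_fraction = min_alt_fraction,
                 min_alt_total = min_alt_total,
                 min_pool_depth = min_pool_depth,
                 ems_only = isTRUE(ems_only)),
            class = "detection_params")
}

#' Default minimum pooled alternate fraction
#'
#' `0.02` for the standard 16-plant pool; `(2/3) / (2 * pool_size)`
#' otherwise, preserving the same margin below the expected heterozygous
#' fraction `1/(2 * pool_size)`.
#'
#' @param pool_size plants per pool.
#' @return minimum alternate fraction.
#' @export
default_min_alt_fraction <- function(pool_size = 16) {
  if (pool_size == 16) 0.02 else (2 / 3) / (2 * pool_size)
}

#' Detect candidate variants in pooled counts
#'
#' Site-wise threshold detection on per-pool allele counts. A pool/site/alt
#' combination is reported iff `alt_count >= min_alt_total`,
#' `alt_count / depth >= min_alt_fraction`, and the pool's total read count
#' is at least `min_pool_depth` (hits in failed libraries are suppressed;
#' the failure is handled downstream as missing data). Only single-base
#' alternates are considered.
#'
#' @param counts a [pool_counts][simulate_pool_counts] data frame.
#' @param params a [detection_params()].
#' @return data frame of pool hits: pool_id, target, position, ref, alt,
#'   alt_count, depth, fraction.
#' @export
detect_pool_variants <- function(counts, params = detection_params()) {
  stopifnot(inherits(params, "detection_params"))
  pool_tot <- tapply(counts$depth, counts$pool_id, sum)
  ok_pool <- names(pool_tot)[pool_tot >= params$min_pool_depth]
  hits <- list()
  for (alt in DNA_BASES) {
    ac <- counts[[alt]]
    sel <- counts$ref != alt &
      ac >= params$min_alt_total &
      counts$depth > 0 &
      ac / counts$depth >= params$min_alt_fraction &
      counts$pool_id %in% ok_pool
    if (any(sel)) {
      hits[[alt]] <- data.frame(
        pool_id = counts$pool_id[sel], target = counts$target[sel],
        position = counts$position[sel], ref = counts$ref[sel],
        alt = alt, alt_count = ac[sel], depth = counts$depth[sel],
        fraction = ac[sel] / counts$depth[sel],
        stringsAsFactors = FALSE
      )
    }
  }
  out <- if (length(hits)) do.call(rbind, hits) else data.frame(
    pool_id = character(), target = character(), position = integer(),
    ref = character(), alt = character(), alt_count = numeric(),
    depth = numeric(), fraction = numeric(), stringsAsFactors = FALSE)
  out <- out[order(out$pool_id, out$target, out$position, out$alt), ]
  rownames(out) <- NULL
  if (isTRUE(params$ems_only)) out <- apply_ems_filter(out)
  out
}

#' Keep only EMS-expected changes
#'
#' EMS alkylates guanine, so induced mutations are overwhelmingly G→A or
#' C→T on the reference strand; this filter drops every other change.
#'
#' @param hits pool-hit data frame (needs `ref` and `alt` columns).
#' @return the filtered data frame.
#' @export
apply_ems_filter <- function(hits) {
  keep <- (hits$ref == "G" & hits$alt == "A") |
    (hits$ref == "C" & hits$alt == "T")
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Flag failed sequencing libraries
#'
#' @param counts a [pool_counts][simulate_pool_counts] data frame.
#' @param min_total_reads threshold on a pool's total read count.
#' @return sorted character vector of pool ids whose total reads fall
#'   below the threshold.
#' @export
flag_failed_pools <- function(counts, min_total_reads = 1000) {
  pool_tot <- tapply(counts$depth, counts$pool_id, sum)
  sort(names(pool_tot)[pool_tot < min_total_reads])
}

#' Re-express external pooled VCF calls as pool hits
#'
#' Adapter from an external pooled caller's per-sample VCF records to the
#' pool-hit layout: VCF sample ids are mapped to pool ids through the
#' sample sheet and fractions recomputed from AD/DP. Detection thresholds
#' are NOT re-applied — they are assumed to have been applied upstream.
#'
#' @param records variant records as from [read_vcf()].
#' @param sheet sample sheet (see [read_sample_sheet()]); its `pool_id`
#'   column must cover every VCF sample id.
#' @return pool-hit data frame as from [detect_pool_variants()].
#' @export
ingest_pool_vcf <- function(records, sheet) {
  i <- match(records$sample_id, sheet$pool_id)
  if (anyNA(i)) {
    .stopf("VCF sample id(s) not in sample sheet: %s",
           paste(unique(records$sample_id[is.na(i)]), collapse = ", "))
  }
  if (any(is.na(records$depth) | records$depth <= 0)) {
    bad <- which(is.na(records$depth) | records$depth <= 0)[1]
    .stopf("record %s:%d sample %s has missing or zero depth",
           records$target[bad], records$position[bad],
           records$sample_id[bad])
  }
  keep <- records$alt_count > 0
  r <- records[keep, , drop = FALSE]
  out <- data.frame(
    pool_id = pool_id(sheet$block[i][keep], sheet$axis[i][keep],
                      sheet$index[i][keep]),
    target = r$target, position = r$position, ref = r$ref, alt = r$alt,
    alt_count = r$alt_count, depth = r$depth,
    fraction = r$alt_count / r$depth,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}
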