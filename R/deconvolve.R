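#' Zygosity inference parameters
#'
#' Expected pooled fractions for an N-plant pool: `1/(2N)` for a
#' heterozygous carrier, `1/N` for a homozygous one. The decision boundary
#' is their midpoint `3/(4N)` — for the standard 16-plant pool 0.046875,
#' separating the observed sub-0.03 heterozygous from sub-0.06 homozygous
#' pooled fractions.
#'
#' @param pool_size plants per pool (default 16).
#' @return object of class `zygosity_params` with fields `pool_size`,
#'   `het_expected`, `hom_expected`, `boundary`.
#' @export
zygosity_params <- function(pool_size = 16) {
  stopifnot(pool_size >= 1)
  structure(list(pool_size = pool_size,
                 het_expected = 1 / (2 * pool_size),
                 hom_expected = 1 / pool_size,
                 boundary = 3 / (4 * pool_size)),
            class = "zygosity_params")
}

#' Infer zygosity from pooled alternate fractions
#'
#' The depth-weighted mean of the row-pool and column-pool alternate
#' fractions is compared to the boundary `3/(4N)`: below or equal means
#' heterozygous (ties break to the more common class), above means
#' homozygous.
#'
#' @param row_fraction,col_fraction alternate fractions in (0, 1).
#' @param params a [zygosity_params()].
#' @param row_depth,col_depth read depths used as weights (equal weights
#'   by default).
#' @return `"het"` or `"hom"`.
#' @export
infer_zygosity <- function(row_fraction, col_fraction,
                           params = zygosity_params(),
                           row_depth = 1, col_depth = 1) {
  stopifnot(inherits(params, "zygosity_params"))
  if (any(c(row_fraction, col_fraction) <= 0) ||
      any(c(row_fraction, col_fraction) >= 1)) {
    .stopf("pooled fractions must lie in (0, 1)")
  }
  mean_f <- (row_fraction * row_depth + col_fraction * col_depth) /
    (row_depth + col_depth)
  ifelse(mean_f > params$boundary, "hom", "het")
}

#' @noRd
.empty_calls <- function() {
  data.frame(target = character(), position = integer(), ref = character(),
             alt = character(), block = integer(), plant_id = character(),
             status = character(), candidate_plants = character(),
             mean_alt_fraction = numeric(), zygosity = character(),
             stringsAsFactors = FALSE)
}

#' Deconvolute one block's pool hits to plant-level calls
#'
#' Applies the twice-per-block rule: a variant is assigned to a plant iff
#' it was detected in exactly one row pool and exactly one column pool of
#' the block; the carrier is the plant at the intersection. Hits on a
#' single axis are rejected (`row_only`/`column_only`), unless the
#' complementary axis contains a failed library, in which case the variant
#' is `undetermined` (the failed pool may have hidden the confirming hit).
#' Hits in two or more pools with both axes represented are `ambiguous`,
#' listing every intersection as a candidate plant. Zygosity is inferred
#' for confirmed calls only (see [infer_zygosity()]).
#'
#' @param hits pool-hit data frame restricted to one block.
#' @param layout the [grid_layout][build_layout].
#' @param failed_pools pool ids of failed libraries in this block.
#' @param zyg_params a [zygosity_params()].
#' @return data frame of calls: target, position, ref, alt, block,
#'   plant_id (NA unless confirmed), status, candidate_plants
#'   (comma-separated, ambiguous only), mean_alt_fraction, zygosity
#'   (confirmed only).
#' @export
deconvolve_block <- function(hits, layout, failed_pools = character(0),
                             zyg_params = zygosity_params()) {
  stopifnot(inherits(layout, "grid_layout"))
  if (nrow(hits) == 0L && length(failed_pools) == 0L) return(.empty_calls())
  pd <- .parse_pool_id(unique(c(hits$pool_id, failed_pools)))
  blocks <- unique(pd$block)
  if (length(blocks) > 1L) {
    .stopf("hits span blocks %s; deconvolve one block at a time",
           paste(blocks, collapse = ", "))
  }
  if (nrow(hits) == 0L) return(.empty_calls())
  b <- blocks
  block_pools <- layout_pools(build_layout(1, layout$n_rows, layout$n_cols))
  block_pools <- sub("^B1_", sprintf("B%d_", b), block_pools)
  bad <- setdiff(hits$pool_id, block_pools)
  if (length(bad)) {
    .stopf("hit references pool %s outside block %d", bad[1], b)
  }
  fp <- .parse_pool_id(failed_pools)
  failed_rows <- fp$index[fp$axis == "row"]
  failed_cols <- fp$index[fp$axis == "column"]

  hp <- .parse_pool_id(hits$pool_id)
  hits$axis <- hp$axis
  hits$index <- hp$index

  vkey <- paste(hits$target, hits$position, hits$ref, hits$alt, sep = "\r")
  out <- lapply(unique(vkey), function(k) {
    h <- hits[vkey == k, , drop = FALSE]
    rows <- unique(h$index[h$axis == "row"])
    cols <- unique(h$index[h$axis == "column"])
    base <- data.frame(target = h$target[1], position = h$position[1],
                       ref = h$ref[1], alt = h$alt[1], block = b,
                       plant_id = NA_character_, status = NA_character_,
                       candidate_plants = NA_character_,
                       mean_alt_fraction = sum(h$fraction * h$depth) /
                         sum(h$depth),
                       zygosity = NA_character_,
                       stringsAsFactors = FALSE)
    if (length(rows) == 1L && length(cols) == 1L) {
      base$status <- "confirmed"
      base$plant_id <- plant_at(layout, b, rows, cols)
      hr <- h[h$axis == "row", ][1, ]
      hc <- h[h$axis == "column", ][1, ]
      base$zygosity <- infer_zygosity(hr$fraction, hc$fraction, zyg_params,
                                      hr$depth, hc$depth)
    } else if (length(rows) >= 1L && length(cols) >= 1L) {
      base$status <- "ambiguous"
      cand <- as.vector(outer(rows, cols, function(r, cc) {
        mapply(function(r1, c1) plant_at(layout, b, r1, c1), r, cc)
      }))
      base$candidate_plants <- paste(sort(cand), collapse = ",")
    } else if (length(rows) >= 1L) {
      base$status <- if (length(failed_cols)) "undetermined" else "row_only"
    } else {
      base$status <- if (length(failed_rows)) "undetermined" else
        "column_only"
    }
    base
  })
  res <- do.call(rbind, out)
  res <- res[order(res$target, res$position, res$alt), ]
  rownames(res) <- NULL
  res
}

#' Deconvolute pool hits across all blocks
#'
#' Splits hits by block, applies [deconvolve_block()] to each, and
#' concatenates. The same variant confirmed in different blocks yields
#' distinct calls (independent plants); merge them afterwards with
#' [collapse_duplicates()].
#'
#' @param hits pool-hit data frame (any blocks).
#' @param layout the [grid_layout][build_layout].
#' @param failed_pools pool ids of failed libraries (any blocks).
#' @param zyg_params a [zygosity_params()].
#' @return calls data frame (see [deconvolve_block()]).
#' @export
deconvolve_calls <- function(hits, layout, failed_pools = character(0),
                             zyg_params = zygosity_params()) {
  if (nrow(hits) == 0L) return(.empty_calls())
  hb <- .parse_pool_id(hits$pool_id)$block
  fb <- if (length(failed_pools)) .parse_pool_id(failed_pools)$block else
    integer(0)
  res <- lapply(sort(unique(hb)), function(b) {
    deconvolve_block(hits[hb == b, , drop = FALSE], layout,
                     failed_pools[fb == b], zyg_params)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Collapse duplicate sibling calls into independent variants
#'
#' Plants grown from the same mutagenised parent carry identical induced
#' mutations; calls are therefore grouped by (target, position, ref, alt)
#' and one record per distinct variant is returned with the list of
#' carrier plants. Idempotent.
#'
#' @param calls calls data frame (confirmed calls are grouped by their
#'   `plant_id`; any data frame with target/position/ref/alt columns
#'   works — carriers default to the `plant_id` column when present).
#' @return data frame: target, position, ref, alt, n_carriers, carriers
#'   (comma-separated plant ids).
#' @export
collapse_duplicates <- function(calls) {
  if (nrow(calls) == 0L) {
    return(data.frame(target = character(), position = integer(),
                      ref = character(), alt = character(),
                      n_carriers = integer(), carriers = character(),
                      stringsAsFactors = FALSE))
  }
  carriers <- if ("carriers" %in% names(calls)) {
    strsplit(ifelse(is.na(calls$carriers), "", calls$carriers), ",")
  } else if ("plant_id" %in% names(calls)) {
    as.list(ifelse(is.na(calls$plant_id), "", calls$plant_id))
  } else {
    rep(list(character(0)), nrow(calls))
  }
  key <- paste(calls$target, calls$position, calls$ref, calls$alt,
               sep = "\r")
  groups <- split(seq_len(nrow(calls)), key)
  # preserve first-appearance order
  groups <- groups[unique(key)]
  out <- do.call(rbind, lapply(groups, function(i) {
    cs <- sort(unique(unlist(carriers[i])))
    cs <- cs[nzchar(cs)]
    data.frame(target = calls$target[i[1]], position = calls$position[i[1]],
               ref = calls$ref[i[1]], alt = calls$alt[i[1]],
               n_carriers = length(cs),
               carriers = paste(cs, collapse = ","),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Score deconvolved calls against simulation truth
#'
#' Sensitivity is the fraction of true (plant, variant) pairs recovered as
#' confirmed calls; the false discovery rate is the fraction of confirmed
#' calls whose (plant, variant) pair is not in the truth; zygosity
#' accuracy is computed over confirmed true pairs. With no confirmed calls
#' the FDR is reported as 0 with `fdr_defined = FALSE`.
#'
#' @param calls calls data frame (see [deconvolve_calls()]).
#' @param truth a [mutant_population][simulate_population].
#' @return list with `sensitivity`, `fdr`, `fdr_defined`,
#'   `zygosity_accuracy`, `n_true`, `n_confirmed`.
#' @export
evaluate_against_truth <- function(calls, truth) {
  stopifnot(inherits(truth, "mutant_population"))
  tm <- truth$mutations
  tkey <- paste(tm$plant_id, tm$target, tm$position, tm$alt, sep = "\r")
  conf <- calls[!is.na(calls$status) & calls$status == "confirmed", ,
                drop = FALSE]
  ckey <- paste(conf$plant_id, conf$target, conf$position, conf$alt,
                sep = "\r")
  tp <- ckey %in% tkey
  sens <- if (length(tkey)) sum(unique(ckey[tp]) %in% tkey) / length(tkey)
    else NA_real_
  fdr_defined <- nrow(conf) > 0
  fdr <- if (fdr_defined) sum(!tp) / nrow(conf) else 0
  zacc <- NA_real_
  if (any(tp)) {
    i <- match(ckey[tp], tkey)
    zacc <- mean(conf$zygosity[tp] == tm$zygosity[i])
  }
  list(sensitivity = sens, fdr = fdr, fdr_defined = fdr_defined,
       zygosity_accuracy = zacc, n_true = length(tkey),
       n_confirmed = nrow(conf))
}
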