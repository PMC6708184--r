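# Shared fixture builders. All fixtures are generated in code; seeds are
# fixed inside each test that draws random numbers.

# a hand-made mutant_population over given targets
make_population <- function(mutations, plants, targets) {
  structure(list(mutations = mutations, plants = plants, targets = targets),
            class = "mutant_population")
}

# a hand-made pool_counts table from (pool, target, position, ref, counts)
make_counts <- function(df) {
  df$depth <- df$A + df$C + df$G + df$T
  structure(df, class = c("pool_counts", "data.frame"),
            pools = unique(df$pool_id))
}

one_count_row <- function(pool_id, ref, alt, alt_count, depth,
                          target = "g1", position = 100L) {
  row <- data.frame(pool_id = pool_id, target = target, position = position,
                    ref = ref, A = 0L, C = 0L, G = 0L, T = 0L,
                    stringsAsFactors = FALSE)
  row[[alt]] <- as.integer(alt_count)
  row[[ref]] <- as.integer(depth - alt_count)
  row
}

# a toy coding gene on a plus-strand target:
#   50 bp 5'UTR-less upstream, single exon covering the CDS, optional intron
# returns list(target = named seq vector, model = gene_model)
toy_coding_gene <- function(cds = "ATGGCATAA", pad5 = 50L, pad3 = 50L,
                            strand = "+", flank_bp = 5000L) {
  seq <- paste0(strrep("A", pad5), cds, strrep("A", pad3))
  tg <- reference_targets(c(gX = seq))
  gm <- gene_model("gX.1", "gX", strand,
                   exons = cbind(pad5 + 1L, pad5 + nchar(cds)),
                   cds = cbind(pad5 + 1L, pad5 + nchar(cds)),
                   flank_bp = flank_bp)
  list(targets = tg, model = gm)
}

# brute-force deconvolution oracle: enumerate every plant of the block and
# keep those whose row pool and column pool both carry the variant
oracle_deconvolve <- function(layout, block, hit_rows, hit_cols,
                              failed_rows = integer(0),
                              failed_cols = integer(0)) {
  plants <- expand.grid(row = seq_len(layout$n_rows),
                        col = seq_len(layout$n_cols))
  cand <- plants[plants$row %in% hit_rows & plants$col %in% hit_cols, ,
                 drop = FALSE]
  if (length(hit_rows) >= 1 && length(hit_cols) >= 1) {
    if (nrow(cand) == 1L) {
      list(status = "confirmed",
           plant = plant_at(layout, block, cand$row, cand$col))
    } else {
      list(status = "ambiguous",
           candidates = sort(mapply(function(r, c)
             plant_at(layout, block, r, c), cand$row, cand$col)))
    }
  } else if (length(hit_rows) >= 1) {
    list(status = if (length(failed_cols)) "undetermined" else "row_only")
  } else if (length(hit_cols) >= 1) {
    list(status = if (length(failed_rows)) "undetermined" else
      "column_only")
  } else {
    list(status = NA_character_)
  }
}

# build a hits data frame for one variant from row/col index sets
hits_for_variant <- function(block, rows, cols, target = "g1",
                             position = 10L, ref = "G", alt = "A",
                             fraction = 0.031, depth = 10000) {
  pools <- c(if (length(rows)) pool_id(rep(block, length(rows)), "row", rows),
             if (length(cols)) pool_id(rep(block, length(cols)), "column",
                                       cols))
  if (length(pools) == 0L) {
    return(data.frame(pool_id = character(), target = character(),
                      position = integer(), ref = character(),
                      alt = character(), alt_count = numeric(),
                      depth = numeric(), fraction = numeric(),
                      stringsAsFactors = FALSE))
  }
  data.frame(pool_id = pools, target = target, position = position,
             ref = ref, alt = alt, alt_count = round(fraction * depth),
             depth = depth, fraction = fraction, stringsAsFactors = FALSE)
}
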