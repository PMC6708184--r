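#' EMS mutation spectrum classes
#'
#' Strand-collapsed substitution classes used throughout: the EMS-typical
#' G/C→A/T transitions, the three next most common classes, and a catch-all
#' for the remaining transversions (G/C→C/G and A/T→C/G).
#' @export
SPECTRUM_CLASSES <- c("GC>AT", "AT>TA", "GC>TA", "AT>GC", "other")

#' Default EMS spectrum
#'
#' Class probabilities typical of a doubly EMS-mutagenised barley
#' population: 79.4% G/C→A/T, 8.1% A/T→T/A, 6.8% G/C→T/A, 3.9% A/T→G/C and
#' 1.8% other events.
#' @export
EMS_SPECTRUM <- c("GC>AT" = 0.794, "AT>TA" = 0.081, "GC>TA" = 0.068,
                  "AT>GC" = 0.039, "other" = 0.018)

# ref base -> alt base per class (strand-resolved)
.CLASS_SUBS <- list(
  "GC>AT" = c(G = "A", C = "T"),
  "AT>TA" = c(A = "T", T = "A"),
  "GC>TA" = c(G = "T", C = "A"),
  "AT>GC" = c(A = "G", T = "C"),
  "other" = c(G = "C", C = "G", A = "C", T = "G")
)

#' Simulation configuration
#'
#' Bundles the parameters of the population and pooled-sequencing
#' simulator. Defaults reproduce the study conditions of a heavily
#' mutagenised diploid TILLING population screened in 16-plant pools:
#' one induced mutation per 154 kb per plant, the EMS-dominated spectrum
#' of [EMS_SPECTRUM], a 60/40 heterozygous/homozygous split, and deep
#' pooled amplicon coverage.
#'
#' @param mutation_rate induced mutations per bp per plant
#'   (default `1/154000`).
#' @param spectrum probability vector over [SPECTRUM_CLASSES]; must sum
#'   to 1 (±1e-9).
#' @param het_fraction probability that a mutation is heterozygous
#'   (default 0.6).
#' @param depth mean reads per pool per site (default 10000).
#' @param error_rate per-base miscall probability (default 1e-3), spread
#'   uniformly over the three non-ref bases.
#' @param imbalance dispersion of per-plant contributions within a pool:
#'   0 is exactly equimolar; otherwise member weights are
#'   Dirichlet(1/imbalance).
#' @param seed integer master seed, or NULL to use the current RNG state.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(mutation_rate = 1 / 154000,
                       spectrum = EMS_SPECTRUM,
                       het_fraction = 0.6,
                       depth = 10000,
                       error_rate = 1e-3,
                       imbalance = 0,
                       seed = NULL) {
  if (length(spectrum) != length(SPECTRUM_CLASSES)) {
    .stopf("spectrum must have %d entries (%s)", length(SPECTRUM_CLASSES),
           paste(SPECTRUM_CLASSES, collapse = ", "))
  }
  if (is.null(names(spectrum))) names(spectrum) <- SPECTRUM_CLASSES
  if (abs(sum(spectrum) - 1) > 1e-9) {
    .stopf("spectrum probabilities sum to %.12f, not 1", sum(spectrum))
  }
  stopifnot(mutation_rate >= 0, het_fraction >= 0, het_fraction <= 1,
            depth >= 0, error_rate >= 0, error_rate < 1, imbalance >= 0)
  structure(list(mutation_rate = mutation_rate,
                 spectrum = spectrum[SPECTRUM_CLASSES],
                 het_fraction = het_fraction, depth = depth,
                 error_rate = error_rate, imbalance = imbalance,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("EMS simulation configuration\n")
  cat(sprintf("  mutation rate : 1 per %.0f bp per plant\n",
              1 / x$mutation_rate))
  cat(sprintf("  spectrum      : %s\n",
              paste(sprintf("%s %.1f%%", names(x$spectrum),
                            100 * x$spectrum), collapse = ", ")))
  cat(sprintf("  het fraction  : %.2f   depth: %g   error: %g   imbalance: %g\n",
              x$het_fraction, x$depth, x$error_rate, x$imbalance))
  invisible(x)
}

#' Generate a random reference target set
#'
#' Uniform-composition DNA, useful as a stand-in genome for simulations.
#'
#' @param lengths named integer vector of target lengths (names become the
#'   target ids; unnamed inputs get `t1`, `t2`, ...).
#' @return named character vector of sequences.
#' @export
random_targets <- function(lengths) {
  if (is.null(names(lengths))) {
    names(lengths) <- paste0("t", seq_along(lengths))
  }
  out <- vapply(lengths, function(L) {
    paste(sample(DNA_BASES, L, replace = TRUE), collapse = "")
  }, character(1))
  reference_targets(out)
}

#' @noRd
.base_at <- function(targets, target, position) {
  out <- character(length(target))
  for (tg in unique(target)) {
    i <- target == tg
    out[i] <- vapply(position[i], function(p) substr(targets[[tg]], p, p),
                     character(1))
  }
  out
}

#' Simulate a mutagenised population
#'
#' Each plant receives a Poisson(`mutation_rate` × total target bp) number
#' of induced mutations. Each mutation draws a substitution class from the
#' configured spectrum and is placed uniformly over the bases eligible for
#' that class (a G/C→A/T event lands only on a G or a C); the alternate
#' base then follows from the reference base and class. Zygosity is
#' Bernoulli(`het_fraction`). A plant never receives two mutations at one
#' site.
#'
#' @param config a [sim_config()].
#' @param targets named character vector of reference sequences.
#' @param layout a [grid_layout][build_layout]; one plant is simulated per
#'   layout cell.
#' @return object of class `mutant_population`: list with `mutations`
#'   (data frame plant_id/target/position/ref/alt/zygosity), `plants`, and
#'   the `targets` used.
#' @export
simulate_population <- function(config, targets, layout) {
  stopifnot(inherits(config, "sim_config"), inherits(layout, "grid_layout"))
  if (length(targets) == 0L) .stopf("no reference targets supplied")
  if (!is.null(config$seed)) set.seed(config$seed)
  lens <- nchar(targets)
  total_bp <- sum(as.numeric(lens))
  cum <- cumsum(as.numeric(lens))
  plants <- layout$plants$plant_id
  n_mut <- rpois(length(plants), config$mutation_rate * total_bp)
  total <- sum(n_mut)

  if (total == 0L) {
    mut <- data.frame(plant_id = character(), target = character(),
                      position = integer(), ref = character(),
                      alt = character(), zygosity = character(),
                      stringsAsFactors = FALSE)
    return(structure(list(mutations = mut, plants = plants,
                          targets = targets),
                     class = "mutant_population"))
  }

  cls <- sample(SPECTRUM_CLASSES, total, replace = TRUE,
                prob = config$spectrum)
  plant_of <- rep(plants, n_mut)

  target_v <- character(total); pos_v <- integer(total)
  ref_v <- character(total)
  todo <- seq_len(total)
  while (length(todo)) {
    u <- ceiling(runif(length(todo)) * total_bp)
    ti <- findInterval(u - 0.5, c(0, cum))
    pos <- as.integer(u - c(0, cum)[ti])
    tg <- names(targets)[ti]
    base <- .base_at(targets, tg, pos)
    ok <- mapply(function(b, cl) b %in% names(.CLASS_SUBS[[cl]]),
                 base, cls[todo])
    hit <- todo[ok]
    target_v[hit] <- tg[ok]; pos_v[hit] <- pos[ok]; ref_v[hit] <- base[ok]
    todo <- todo[!ok]
  }
  alt_v <- mapply(function(b, cl) .CLASS_SUBS[[cl]][[b]], ref_v, cls)
  zyg <- ifelse(runif(total) < config$het_fraction, "het", "hom")

  mut <- data.frame(plant_id = plant_of, target = target_v,
                    position = pos_v, ref = ref_v, alt = unname(alt_v),
                    zygosity = zyg, stringsAsFactors = FALSE)
  # a plant never carries two alts at one site: drop later duplicates
  dup <- duplicated(mut[c("plant_id", "target", "position")])
  if (any(dup)) mut <- mut[!dup, , drop = FALSE]
  mut <- mut[order(mut$plant_id, mut$target, mut$position), ]
  rownames(mut) <- NULL
  structure(list(mutations = mut, plants = plants, targets = targets),
            class = "mutant_population")
}

#' @export
print.mutant_population <- function(x, ...) {
  cat(sprintf("Mutant population: %d plants, %d mutations over %d target(s) (%s bp)\n",
              length(x$plants), nrow(x$mutations), length(x$targets),
              format(sum(nchar(x$targets)), big.mark = ",")))
  if (nrow(x$mutations)) {
    z <- table(x$mutations$zygosity)
    cat(sprintf("  zygosity: %s\n",
                paste(sprintf("%s %d", names(z), z), collapse = ", ")))
  }
  invisible(x)
}

#' @export
summary.mutant_population <- function(object, ...) {
  m <- object$mutations
  list(n_plants = length(object$plants),
       n_mutations = nrow(m),
       per_plant = if (nrow(m)) as.vector(table(factor(m$plant_id,
                                                       object$plants))) else
         rep(0L, length(object$plants)),
       spectrum = spectrum_table(m),
       het_fraction = if (nrow(m)) mean(m$zygosity == "het") else NA_real_)
}

#' Expected pooled alternate-allele fraction
#'
#' In an equimolar pool of `pool_size` diploid plants a single carrier
#' contributes `dosage` of the `2 * pool_size` chromosomes: 1/32 for a
#' heterozygote and 1/16 for a homozygote at the standard pool size 16.
#'
#' @param zygosity `"het"` or `"hom"` (vectorised).
#' @param pool_size plants per pool (default 16).
#' @return expected alternate fraction.
#' @export
pooled_alt_fraction <- function(zygosity, pool_size = 16) {
  dosage <- ifelse(zygosity == "hom", 2, 1)
  dosage / (2 * pool_size)
}

#' Instantiate substitution classes as concrete base changes
#'
#' Maps strand-collapsed class labels to reference-strand (ref, alt) base
#' pairs, choosing the strand orientation uniformly at random (a `GC>AT`
#' event becomes G→A or C→T with equal probability, and so on).
#'
#' @param classes character vector of [SPECTRUM_CLASSES] labels.
#' @return data frame with `ref` and `alt` columns.
#' @export
instantiate_spectrum <- function(classes) {
  bad <- setdiff(unique(classes), SPECTRUM_CLASSES)
  if (length(bad)) .stopf("unknown spectrum class: %s", bad[1])
  ref <- vapply(classes, function(cl) {
    sample(names(.CLASS_SUBS[[cl]]), 1)
  }, character(1), USE.NAMES = FALSE)
  alt <- mapply(function(b, cl) .CLASS_SUBS[[cl]][[b]], ref, classes)
  data.frame(ref = ref, alt = unname(alt), stringsAsFactors = FALSE)
}

#' Clone a plant's mutations into sibling plants
#'
#' Plants grown from bulk-harvested seed of one mutagenised parent share
#' that parent's induced mutations; cloning emulates such duplicate
#' sibling lines so that duplicate collapse can be exercised.
#'
#' @param population a [mutant_population][simulate_population].
#' @param donor plant id whose mutation set is copied.
#' @param recipients plant ids whose mutation sets are replaced by the
#'   donor's.
#' @return the modified population.
#' @export
clone_siblings <- function(population, donor, recipients) {
  stopifnot(inherits(population, "mutant_population"))
  bad <- setdiff(c(donor, recipients), population$plants)
  if (length(bad)) .stopf("unknown plant(s): %s", paste(bad, collapse = ", "))
  m <- population$mutations
  keep <- m[!m$plant_id %in% recipients, , drop = FALSE]
  donor_m <- m[m$plant_id == donor, , drop = FALSE]
  clones <- do.call(rbind, lapply(recipients, function(p) {
    d <- donor_m; if (nrow(d)) d$plant_id <- p; d
  }))
  m2 <- rbind(keep, clones)
  m2 <- m2[order(m2$plant_id, m2$target, m2$position), ]
  rownames(m2) <- NULL
  population$mutations <- m2
  population
}

#' Simulate pooled per-site read counts
#'
#' For every pool of the layout and every site of every target, the true
#' pooled alternate fraction is the weighted allele dosage of the pool
#' members, `f = sum(w_i * dosage_i) / 2` with weights `w_i` equimolar
#' (`1/N`) or Dirichlet-perturbed when `imbalance > 0`. Sequencing error
#' moves each read to one of the three other bases with probability
#' `error_rate/3` each, and observed counts at a site are multinomial with
#' a Poisson(`depth`) total, so allele counts always sum to the site depth.
#'
#' Reproducibility: with a non-NULL `config$seed` each block is generated
#' from its own substream (`seed + 1000 + block`), so blocks can be
#' regenerated independently.
#'
#' @param population a [mutant_population][simulate_population].
#' @param layout the [grid_layout][build_layout] the population was
#'   simulated on.
#' @param targets named character vector of reference sequences.
#' @param config a [sim_config()].
#' @return object of class `pool_counts`: data frame with columns
#'   pool_id, target, position, ref, A, C, G, T, depth.
#' @export
simulate_pool_counts <- function(population, layout, targets, config) {
  stopifnot(inherits(population, "mutant_population"),
            inherits(layout, "grid_layout"),
            inherits(config, "sim_config"))
  extra <- setdiff(unique(population$mutations$plant_id),
                   layout$plants$plant_id)
  if (length(extra)) {
    .stopf("population plant(s) absent from layout: %s",
           paste(head(extra, 3), collapse = ", "))
  }
  lens <- nchar(targets)
  site_target <- rep(names(targets), lens)
  site_pos <- unlist(lapply(lens, seq_len), use.names = FALSE)
  site_ref <- unlist(strsplit(targets, ""), use.names = FALSE)
  n_sites <- length(site_pos)
  site_key <- paste(site_target, site_pos)

  blocks <- lapply(seq_len(layout$n_blocks), function(b) {
    if (!is.null(config$seed)) set.seed(config$seed + 1000L + b)
    .simulate_block_counts(b, population, layout, config,
                           site_target, site_pos, site_ref, site_key,
                           n_sites)
  })
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  structure(out, class = c("pool_counts", "data.frame"),
            pools = layout_pools(layout))
}

#' @noRd
.simulate_block_counts <- function(b, population, layout, config,
                                   site_target, site_pos, site_ref,
                                   site_key, n_sites) {
  pools_r <- pool_id(rep(b, layout$n_rows), "row", seq_len(layout$n_rows))
  pools_c <- pool_id(rep(b, layout$n_cols), "column", seq_len(layout$n_cols))
  pools <- c(pools_r, pools_c)
  n_pools <- length(pools)

  # per-pool member weights
  weights <- lapply(pools, function(p) {
    mem <- pool_members(layout, p)
    w <- if (config$imbalance > 0) {
      g <- rgamma(length(mem), shape = 1 / config$imbalance)
      g / sum(g)
    } else rep(1 / length(mem), length(mem))
    setNames(w, mem)
  })
  names(weights) <- pools

  # true alternate fractions, one matrix per alt base: n_pools x n_sites
  f <- lapply(DNA_BASES, function(b) matrix(0, n_pools, n_sites))
  names(f) <- DNA_BASES
  pl <- layout$plants
  block_plants <- pl$plant_id[pl$block == b]
  m <- population$mutations
  m <- m[m$plant_id %in% block_plants, , drop = FALSE]
  if (nrow(m)) {
    si <- match(paste(m$target, m$position), site_key)
    if (anyNA(si)) .stopf("mutation at unknown site %s:%d",
                          m$target[is.na(si)][1], m$position[is.na(si)][1])
    dos <- ifelse(m$zygosity == "hom", 2, 1)
    prow <- match(m$plant_id, pl$plant_id)
    rp <- match(pool_id(b, "row", pl$row[prow]), pools)
    cp <- match(pool_id(b, "column", pl$col[prow]), pools)
    for (i in seq_len(nrow(m))) {
      a <- m$alt[i]
      wr <- weights[[rp[i]]][[m$plant_id[i]]]
      wc <- weights[[cp[i]]][[m$plant_id[i]]]
      f[[a]][rp[i], si[i]] <- f[[a]][rp[i], si[i]] + wr * dos[i] / 2
      f[[a]][cp[i], si[i]] <- f[[a]][cp[i], si[i]] + wc * dos[i] / 2
    }
  }

  # fold in the reference fraction and the symmetric error model
  e <- config$error_rate
  refmat <- matrix(rep(site_ref, each = n_pools), n_pools, n_sites)
  p_alt_sum <- f$A + f$C + f$G + f$T
  q <- lapply(DNA_BASES, function(bb) {
    p <- f[[bb]] + (refmat == bb) * (1 - p_alt_sum)
    p * (1 - e) + (1 - p) * (e / 3)
  })
  names(q) <- DNA_BASES

  depth <- matrix(rpois(n_pools * n_sites, config$depth), n_pools, n_sites)
  # sequential binomial decomposition of the multinomial draw
  qa <- q$A; qc <- q$C; qg <- q$G; qt <- q$T
  nA <- .rbinom_mat(depth, qa / (qa + qc + qg + qt))
  rem <- depth - nA
  nC <- .rbinom_mat(rem, qc / (qc + qg + qt))
  rem <- rem - nC
  nG <- .rbinom_mat(rem, qg / (qg + qt))
  nT <- rem - nG

  data.frame(
    pool_id = rep(pools, n_sites),
    target = rep(site_target, each = n_pools),
    position = rep(site_pos, each = n_pools),
    ref = rep(site_ref, each = n_pools),
    A = as.vector(nA), C = as.vector(nC),
    G = as.vector(nG), T = as.vector(nT),
    depth = as.vector(depth),
    stringsAsFactors = FALSE
  )
}

#' @noRd
.rbinom_mat <- function(size, prob) {
  p <- ifelse(is.finite(prob), prob, 0)
  out <- rbinom(length(size), as.vector(size), as.vector(p))
  matrix(out, nrow(size), ncol(size))
}

#' @export
print.pool_counts <- function(x, ...) {
  cat(sprintf("Pooled read counts: %d pools x %d sites\n",
              length(unique(x$pool_id)),
              length(unique(paste(x$target, x$position)))))
  cat(sprintf("  mean site depth %.0f reads\n", mean(x$depth)))
  invisible(x)
}

#' Degrade listed pools to a residual depth (library failure)
#'
#' Emulates failed sequencing libraries: reads of the listed pools are
#' down-sampled so that each pool's total read count is approximately
#' `residual_depth` (binomial thinning site by site); all other pools are
#' untouched. `residual_depth = 0` zeroes the pools.
#'
#' @param counts a [pool_counts][simulate_pool_counts] object.
#' @param pool_ids pools to fail.
#' @param residual_depth target total reads per failed pool.
#' @return the modified `pool_counts`.
#' @export
inject_pool_failure <- function(counts, pool_ids, residual_depth) {
  stopifnot(inherits(counts, "pool_counts"))
  if (length(pool_ids) == 0L) return(counts)
  known <- unique(counts$pool_id)
  bad <- setdiff(pool_ids, known)
  if (length(bad)) .stopf("unknown pool(s): %s", paste(bad, collapse = ", "))
  for (p in pool_ids) {
    i <- which(counts$pool_id == p)
    tot <- sum(counts$depth[i])
    keep_p <- if (tot > 0) min(1, residual_depth / tot) else 0
    for (bcol in DNA_BASES) {
      counts[[bcol]][i] <- rbinom(length(i), counts[[bcol]][i], keep_p)
    }
    counts$depth[i] <- counts$A[i] + counts$C[i] + counts$G[i] + counts$T[i]
  }
  counts
}
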