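#' Strand-collapsed mutation spectrum
#'
#' Classifies SNVs into the five strand-collapsed classes of
#' [SPECTRUM_CLASSES] (complementary changes count together: G→A with
#' C→T, A→T with T→A, and so on; G/C→C/G and A/T→C/G transversions fall
#' into `other`) and tabulates counts and fractions.
#'
#' @param mutations data frame with single-base `ref` and `alt` columns
#'   on the reference strand.
#' @return object of class `spectrum_table`: data frame class/count/
#'   fraction.
#' @export
spectrum_table <- function(mutations) {
  ref <- mutations$ref; alt <- mutations$alt
  if (length(ref) && any(!.is_snv(ref, alt))) {
    bad <- which(!.is_snv(ref, alt))[1]
    .stopf("non-SNV input at row %d (%s>%s)", bad, ref[bad], alt[bad])
  }
  cls <- rep("other", length(ref))
  cls[(ref == "G" & alt == "A") | (ref == "C" & alt == "T")] <- "GC>AT"
  cls[(ref == "A" & alt == "T") | (ref == "T" & alt == "A")] <- "AT>TA"
  cls[(ref == "G" & alt == "T") | (ref == "C" & alt == "A")] <- "GC>TA"
  cls[(ref == "A" & alt == "G") | (ref == "T" & alt == "C")] <- "AT>GC"
  tab <- table(factor(cls, levels = SPECTRUM_CLASSES))
  out <- data.frame(class = SPECTRUM_CLASSES, count = as.integer(tab),
                    fraction = if (length(ref)) as.numeric(tab) / length(ref)
                      else rep(NA_real_, length(tab)),
                    stringsAsFactors = FALSE)
  structure(out, class = c("spectrum_table", "data.frame"))
}

#' @export
print.spectrum_table <- function(x, ...) {
  cat("Mutation spectrum (strand-collapsed)\n")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-6s %8d  %6.1f%%\n", x$class[i], x$count[i],
                100 * x$fraction[i]))
  }
  invisible(x)
}

#' Mutation density in kb of covered sequence per mutation
#'
#' `covered_bp / (n_mutations / n_plants) / 1000`: the kilobases of
#' screened sequence containing, on average, one induced mutation per
#' plant. With no mutations an explicit sentinel is returned instead of a
#' division error.
#'
#' @param n_mutations total mutations over all plants.
#' @param covered_bp screened sequence length in bp.
#' @param n_plants number of plants.
#' @return list with `kb_per_mutation` (NA when `n_mutations == 0`),
#'   `no_mutations` flag, and the three inputs.
#' @export
mutation_density <- function(n_mutations, covered_bp, n_plants) {
  stopifnot(covered_bp > 0, n_plants >= 1, n_mutations >= 0)
  if (n_mutations == 0) {
    return(list(kb_per_mutation = NA_real_, no_mutations = TRUE,
                n_mutations = 0, covered_bp = covered_bp,
                n_plants = n_plants))
  }
  list(kb_per_mutation = covered_bp / (n_mutations / n_plants) / 1000,
       no_mutations = FALSE, n_mutations = n_mutations,
       covered_bp = covered_bp, n_plants = n_plants)
}

#' Expected plants to screen per mutation in a gene
#'
#' At a density of one mutation per `density_kb_per_mutation` kb per
#' plant, a gene of `gene_length_kb` kb carries a mutation in one plant
#' out of `density / length` on average (2 kb at 1/154 kb: 77 plants).
#'
#' @param gene_length_kb gene (or screened fragment) length in kb.
#' @param density_kb_per_mutation mutation density, kb per mutation.
#' @return expected number of plants per mutation, unrounded.
#' @export
plants_to_screen <- function(gene_length_kb, density_kb_per_mutation) {
  stopifnot(gene_length_kb > 0, density_kb_per_mutation > 0)
  density_kb_per_mutation / gene_length_kb
}

#' Exome-capture hard-filter parameters
#'
#' @param min_reads_per_sample per-sample depth below which a sample is
#'   treated as missing at a site (default 4).
#' @param min_informative_samples minimum samples with sufficient depth
#'   for a site to be kept (default 15, of a 20-plant panel).
#' @param drop_indels remove non-SNV records (default TRUE).
#' @param max_qd reject sites with `QD <` this (default 2.0).
#' @param max_fs,max_sor reject sites with `FS >` max_fs AND `SOR >`
#'   max_sor jointly (defaults 20.0 and 4.0).
#' @param unique_position keep only positions where a single plant
#'   carries the variant (default TRUE); shared positions are treated as
#'   probable pre-existing polymorphism or outcrossing.
#' @param het_min_alt_fraction per-individual heterozygous alternate
#'   fraction threshold (default 0.40), used by [het_fraction_filter()].
#' @return object of class `exome_filter_params`.
#' @export
exome_filter_params <- function(min_reads_per_sample = 4,
                                min_informative_samples = 15,
                                drop_indels = TRUE,
                                max_qd = 2.0, max_fs = 20.0, max_sor = 4.0,
                                unique_position = TRUE,
                                het_min_alt_fraction = 0.40) {
  stopifnot(min_reads_per_sample > 0, min_informative_samples > 0)
  structure(list(min_reads_per_sample = min_reads_per_sample,
                 min_informative_samples = min_informative_samples,
                 drop_indels = isTRUE(drop_indels), max_qd = max_qd,
                 max_fs = max_fs, max_sor = max_sor,
                 unique_position = isTRUE(unique_position),
                 het_min_alt_fraction = het_min_alt_fraction),
            class = "exome_filter_params")
}

#' Hard-filter cascade for multi-sample exome-capture variants
#'
#' Applies, in order: indel removal; per-sample genotypes with depth below
#' `min_reads_per_sample` set missing; sites informative (sufficient
#' depth) in fewer than `min_informative_samples` samples dropped; sites
#' with `QD < max_qd` dropped; sites with `FS > max_fs` AND
#' `SOR > max_sor` dropped; and finally positions where more than one
#' plant carries a variant dropped entirely. Sites missing an INFO
#' annotation pass that predicate with a warning. The result does not
#' depend on input row order.
#'
#' @param records variant records as from [read_vcf()] — one row per
#'   (site, alt, sample) with `depth`, `alt_count`, `QD`, `FS`, `SOR`.
#' @param params an [exome_filter_params()].
#' @return the surviving records (rows with sufficient per-sample depth at
#'   surviving sites), ordered by target/position/alt/sample.
#' @export
exome_filter <- function(records, params = exome_filter_params()) {
  stopifnot(inherits(params, "exome_filter_params"))
  r <- records
  if (params$drop_indels && nrow(r)) {
    r <- r[.is_snv(r$ref, r$alt), , drop = FALSE]
  }
  if (nrow(r) == 0L) return(r[order(r$target), , drop = FALSE])
  # samples below the depth floor are missing at that site
  informative <- !is.na(r$depth) & r$depth >= params$min_reads_per_sample
  site <- paste(r$target, r$position, r$alt, sep = "\r")
  n_inf <- tapply(informative, site, sum)
  keep_site <- names(n_inf)[n_inf >= params$min_informative_samples]
  r <- r[site %in% keep_site & informative, , drop = FALSE]
  if (nrow(r) == 0L) return(r)

  site <- paste(r$target, r$position, r$alt, sep = "\r")
  site_first <- !duplicated(site)
  miss_info <- character(0)
  qd <- r$QD[site_first]
  if (anyNA(qd)) miss_info <- c(miss_info, "QD")
  drop_qd <- !is.na(qd) & qd < params$max_qd
  fs <- r$FS[site_first]; sor <- r$SOR[site_first]
  if (anyNA(fs)) miss_info <- c(miss_info, "FS")
  if (anyNA(sor)) miss_info <- c(miss_info, "SOR")
  drop_fs <- !is.na(fs) & !is.na(sor) &
    fs > params$max_fs & sor > params$max_sor
  if (length(miss_info)) {
    warning(sprintf("missing INFO key(s) %s at some sites; those sites pass the corresponding predicate",
                    paste(unique(miss_info), collapse = ", ")),
            call. = FALSE)
  }
  bad_sites <- unique(site)[drop_qd | drop_fs]
  r <- r[!site %in% bad_sites, , drop = FALSE]
  if (nrow(r) == 0L) return(r)

  if (params$unique_position) {
    carrier <- r$alt_count > 0
    posk <- paste(r$target, r$position, sep = "\r")
    n_carriers <- tapply(ifelse(carrier, r$sample_id, NA_character_), posk,
                         function(x) length(unique(x[!is.na(x)])))
    shared <- names(n_carriers)[n_carriers > 1]
    r <- r[!posk %in% shared, , drop = FALSE]
  }
  r <- r[order(r$target, r$position, r$alt, r$sample_id), , drop = FALSE]
  rownames(r) <- NULL
  r
}

#' Per-individual heterozygous allele-fraction filter
#'
#' In individual (non-pooled) libraries a genuine heterozygous call should
#' carry the alternate allele in roughly half the reads; heterozygous
#' records are kept iff `alt_count / depth >= min_fraction`. Homozygous
#' records are unaffected.
#'
#' @param records variant records with `gt`, `alt_count`, `depth`.
#' @param min_fraction threshold (default 0.40).
#' @return the surviving records.
#' @export
het_fraction_filter <- function(records, min_fraction = 0.40) {
  if (nrow(records) == 0L) return(records)
  het <- .is_het_gt(records$gt)
  frac <- ifelse(records$depth > 0, records$alt_count / records$depth, 0)
  keep <- !het | frac >= min_fraction
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @noRd
.is_het_gt <- function(gt) {
  a <- strsplit(ifelse(is.na(gt), "./.", gt), "[/|]")
  vapply(a, function(x) length(unique(x)) > 1L && !any(x == "."), logical(1))
}

#' Capture-probe tiling arithmetic
#'
#' Probes of `probe_len` nt are laid across each target at a step of
#' `round(probe_len / tiling)` bp (3x-tiling of 80-nt probes steps 27 bp).
#' If the last regular probe falls short of the target end, one extra
#' probe is anchored at the end. Targets shorter than a probe get a single
#' end-anchored probe, with a warning.
#'
#' @param target_lengths named or unnamed integer vector of target lengths
#'   in bp.
#' @param probe_len probe size in nt (default 80).
#' @param tiling tiling density (default 3).
#' @return list with `per_target` (data frame target/length/n_probes) and
#'   `total`.
#' @export
design_probes <- function(target_lengths, probe_len = 80L, tiling = 3L) {
  stopifnot(tiling >= 1, probe_len >= 1)
  step <- round(probe_len / tiling)
  n <- vapply(target_lengths, function(L) {
    if (L < probe_len) {
      warning(sprintf("target of %d bp shorter than the %d nt probe; one end-anchored probe used",
                      L, probe_len), call. = FALSE)
      return(1L)
    }
    k <- as.integer((L - probe_len) %/% step + 1L)
    if ((k - 1L) * step + probe_len < L) k <- k + 1L  # end-anchored probe
    k
  }, integer(1))
  per_target <- data.frame(
    target = if (is.null(names(target_lengths)))
      paste0("t", seq_along(target_lengths)) else names(target_lengths),
    length = as.integer(target_lengths), n_probes = n,
    stringsAsFactors = FALSE)
  list(per_target = per_target, total = sum(n), probe_len = probe_len,
       tiling = tiling, step = step)
}
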