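#' Effect categories ordered by severity
#'
#' Used to pick the headline annotation when a variant overlaps several
#' gene models.
#' @export
EFFECT_SEVERITY <- c("nonsense", "splice_site", "missense", "synonymous",
                     "utr5", "utr3", "intron", "upstream", "downstream",
                     "intergenic")

#' Construct a gene model
#'
#' A single-transcript gene model on one reference target: ordered,
#' non-overlapping exons, an optional CDS (subset of the exons, total
#' length divisible by 3), and a flanking window within which variants are
#' annotated as up/downstream rather than intergenic.
#'
#' All coordinates are 1-based and inclusive, as in GFF3.
#'
#' @param gene_id identifier.
#' @param target reference target name.
#' @param strand `"+"` or `"-"`.
#' @param exons two-column matrix (start, end) of exon intervals.
#' @param cds two-column matrix of coding intervals, or NULL for a
#'   non-coding model.
#' @param flank_bp up/downstream window (default 5000, the SnpEff
#'   convention).
#' @return object of class `gene_model`.
#' @export
gene_model <- function(gene_id, target, strand, exons, cds = NULL,
                       flank_bp = 5000L) {
  strand <- match.arg(strand, c("+", "-"))
  exons <- matrix(as.integer(exons), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  exons <- exons[order(exons[, 1]), , drop = FALSE]
  if (any(exons[, 2] < exons[, 1])) .stopf("exon end before start")
  if (nrow(exons) > 1L &&
      any(exons[-1, 1] <= exons[-nrow(exons), 2])) {
    .stopf("exons overlap or touch in gene %s", gene_id)
  }
  if (!is.null(cds)) {
    cds <- matrix(as.integer(cds), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
    cds <- cds[order(cds[, 1]), , drop = FALSE]
    inside <- vapply(seq_len(nrow(cds)), function(i) {
      any(cds[i, 1] >= exons[, 1] & cds[i, 2] <= exons[, 2])
    }, logical(1))
    if (!all(inside)) .stopf("CDS interval outside exons in gene %s", gene_id)
    clen <- sum(cds[, 2] - cds[, 1] + 1L)
    if (clen %% 3L != 0L) {
      .stopf("CDS length %d of gene %s not divisible by 3", clen, gene_id)
    }
  }
  structure(list(gene_id = gene_id, target = target, strand = strand,
                 exons = exons, cds = cds,
                 flank_bp = as.integer(flank_bp)),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("Gene model %s on %s (%s): %d exon(s), %s, span %d-%d\n",
              x$gene_id, x$target, x$strand, nrow(x$exons),
              if (is.null(x$cds)) "non-coding" else
                sprintf("CDS %d bp", sum(x$cds[, 2] - x$cds[, 1] + 1)),
              min(x$exons[, 1]), max(x$exons[, 2])))
  invisible(x)
}

#' @noRd
.cds_sequence <- function(model, reference) {
  seq <- reference[[model$target]]
  pieces <- apply(model$cds, 1, function(iv) substr(seq, iv[1], iv[2]))
  s <- paste(pieces, collapse = "")
  if (model$strand == "-") s <- .revcomp(s)
  s
}

#' @noRd
.cds_offset <- function(model, position) {
  # 1-based position within the coding sequence, on the coding strand
  cds <- model$cds
  lens <- cds[, 2] - cds[, 1] + 1L
  i <- which(position >= cds[, 1] & position <= cds[, 2])
  if (length(i) != 1L) return(NA_integer_)
  fwd <- sum(lens[seq_len(i - 1L)]) + (position - cds[i, 1] + 1L)
  if (model$strand == "+") fwd else sum(lens) - fwd + 1L
}

#' @noRd
.translate_codon <- function(codon) {
  unname(Biostrings::GENETIC_CODE[codon])
}

#' Annotate a single-nucleotide variant against a gene model
#'
#' Categories are assigned by position with the precedence splice site >
#' CDS effect > UTR > intron > flank > intergenic. Splice sites are the
#' first and last two bases of each intron (canonical GT/AG). Coding
#' effects are determined by translating the affected codon on the coding
#' strand: a gained stop is `nonsense`, an amino-acid change `missense`,
#' otherwise `synonymous`. Start-codon loss and stop-codon loss have no
#' category of their own and are reported as `missense` with a note.
#'
#' @param variant list or one-row data frame with `target`, `position`,
#'   `ref`, `alt` (single bases, reference strand).
#' @param model a [gene_model()].
#' @param reference named character vector of target sequences.
#' @return one-row data frame: gene_id, category, codon_change, aa_change,
#'   note.
#' @export
annotate_variant <- function(variant, model, reference) {
  stopifnot(inherits(model, "gene_model"))
  v <- as.list(variant)
  if (!v$target %in% names(reference)) {
    .stopf("variant target '%s' not in reference", v$target)
  }
  seq <- reference[[v$target]]
  if (v$position < 1L || v$position > nchar(seq)) {
    .stopf("variant position %d outside target %s (length %d)",
           v$position, v$target, nchar(seq))
  }
  obs <- substr(seq, v$position, v$position)
  if (obs != v$ref) {
    .stopf("reference mismatch at %s:%d — expected %s, reference has %s",
           v$target, v$position, v$ref, obs)
  }
  ann <- function(category, codon_change = NA_character_,
                  aa_change = NA_character_, note = NA_character_) {
    data.frame(gene_id = if (category == "intergenic") NA_character_ else
                 model$gene_id,
               category = category, codon_change = codon_change,
               aa_change = aa_change, note = note,
               stringsAsFactors = FALSE)
  }
  if (v$target != model$target) return(ann("intergenic"))
  pos <- v$position
  ex <- model$exons
  gs <- min(ex[, 1]); ge <- max(ex[, 2])

  # splice sites: first/last 2 bases of each intron
  if (nrow(ex) > 1L) {
    for (i in seq_len(nrow(ex) - 1L)) {
      is <- ex[i, 2] + 1L; ie <- ex[i + 1L, 1] - 1L
      if (pos >= is && pos <= ie) {
        if (pos <= min(is + 1L, ie) || pos >= max(ie - 1L, is)) {
          return(ann("splice_site"))
        }
        break
      }
    }
  }

  in_cds <- !is.null(model$cds) &&
    any(pos >= model$cds[, 1] & pos <= model$cds[, 2])
  if (in_cds) {
    cds_seq <- .cds_sequence(model, reference)
    off <- .cds_offset(model, pos)
    alt_coding <- if (model$strand == "+") v$alt else .complement(v$alt)
    codon_i <- (off - 1L) %/% 3L + 1L
    within <- (off - 1L) %% 3L + 1L
    codon <- substr(cds_seq, 3L * (codon_i - 1L) + 1L, 3L * codon_i)
    codon_mut <- codon
    substr(codon_mut, within, within) <- alt_coding
    aa_ref <- .translate_codon(codon)
    aa_alt <- .translate_codon(codon_mut)
    cchg <- sprintf("%s>%s", codon, codon_mut)
    achg <- sprintf("%s%d%s", aa_ref, codon_i, aa_alt)
    if (aa_alt == "*" && aa_ref != "*") {
      return(ann("nonsense", cchg, achg))
    }
    if (aa_alt == aa_ref) return(ann("synonymous", cchg, achg))
    note <- if (codon_i == 1L && codon == "ATG") "start_loss" else
      if (aa_ref == "*") "stop_loss" else NA_character_
    return(ann("missense", cchg, achg, note))
  }

  in_exon <- any(pos >= ex[, 1] & pos <= ex[, 2])
  if (in_exon) {
    if (is.null(model$cds)) {
      # non-coding transcript: everything exonic is untranslated
      return(ann("utr3", note = "non_coding_transcript"))
    }
    cs <- min(model$cds[, 1]); ce <- max(model$cds[, 2])
    before <- pos < cs
    five_prime <- if (model$strand == "+") before else !before
    return(ann(if (five_prime) "utr5" else "utr3"))
  }
  if (pos >= gs && pos <= ge) return(ann("intron"))

  if (pos < gs && gs - pos <= model$flank_bp) {
    return(ann(if (model$strand == "+") "upstream" else "downstream"))
  }
  if (pos > ge && pos - ge <= model$flank_bp) {
    return(ann(if (model$strand == "+") "downstream" else "upstream"))
  }
  ann("intergenic")
}

#' Annotate many variants against many gene models
#'
#' Each variant receives one annotation per gene model, plus (when
#' `most_severe = TRUE`) the single headline annotation: among models
#' whose annotation is not intergenic, the most severe category by
#' [EFFECT_SEVERITY] wins; a gene-body feature always beats a neighbouring
#' gene's flank.
#'
#' @param variants data frame with target, position, ref, alt.
#' @param models list of [gene_model()] objects.
#' @param reference named character vector of target sequences.
#' @param most_severe return only the headline row per variant.
#' @return data frame: variant columns + gene_id, category, codon_change,
#'   aa_change, note.
#' @export
annotate_variants <- function(variants, models, reference,
                              most_severe = TRUE) {
  if (inherits(models, "gene_model")) models <- list(models)
  rows <- lapply(seq_len(nrow(variants)), function(i) {
    v <- variants[i, , drop = FALSE]
    anns <- do.call(rbind, lapply(models, annotate_variant,
                                  variant = v, reference = reference))
    if (most_severe) {
      sev <- match(anns$category, EFFECT_SEVERITY)
      anns <- anns[which.min(sev), , drop = FALSE]
    }
    cbind(v[rep(1L, nrow(anns)), c("target", "position", "ref", "alt"),
            drop = FALSE], anns)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarise effect categories
#'
#' @param annotations data frame with a `category` column.
#' @return data frame category/count/fraction; fractions sum to 1 over the
#'   annotated variants.
#' @export
summarize_effects <- function(annotations) {
  cats <- factor(annotations$category, levels = EFFECT_SEVERITY)
  tab <- table(cats)
  data.frame(category = names(tab), count = as.integer(tab),
             fraction = if (sum(tab) > 0) as.numeric(tab) / sum(tab) else
               rep(0, length(tab)),
             stringsAsFactors = FALSE)
}
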