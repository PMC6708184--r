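test_that("coding changes classify by codon translation", {
  fx <- toy_coding_gene("ATGGCATAA")   # Met-Ala-Stop starting at 51
  v <- function(pos, ref, alt) list(target = "gX", position = pos,
                                    ref = ref, alt = alt)
  # codon 2 GCA -> ACA : Ala -> Thr, missense
  a <- annotate_variant(v(54L, "G", "A"), fx$model, fx$targets)
  expect_equal(a$category, "missense")
  expect_equal(a$aa_change, "A2T")
  expect_equal(a$codon_change, "GCA>ACA")

  # CAA -> TAA : stop gained, nonsense
  fq <- toy_coding_gene("ATGCAATAA")
  n <- annotate_variant(v(54L, "C", "T"), fq$model, fq$targets)
  expect_equal(n$category, "nonsense")
  expect_equal(n$aa_change, "Q2*")

  # GGC -> GGT : third position, synonymous
  fg <- toy_coding_gene("ATGGGCTAA")
  s <- annotate_variant(v(56L, "C", "T"), fg$model, fg$targets)
  expect_equal(s$category, "synonymous")

  # start-codon loss is missense with a note
  sl <- annotate_variant(v(51L, "A", "G"), fx$model, fx$targets)
  expect_equal(sl$category, "missense")
  expect_equal(sl$note, "start_loss")
})

test_that("splice sites, introns, UTRs and flanks are positional", {
  # two-exon gene: exon 101-160, intron 161-220, exon 221-310
  seq <- strrep("A", 6000)
  substr(seq, 161, 162) <- "GT"; substr(seq, 219, 220) <- "AG"
  tg <- reference_targets(c(gX = seq))
  gm <- gene_model("gX.1", "gX", "+",
                   exons = rbind(c(101L, 160L), c(221L, 310L)),
                   cds = rbind(c(121L, 160L), c(221L, 300L)))
  v <- function(pos) list(target = "gX", position = pos,
                          ref = substr(seq, pos, pos), alt = "C")
  expect_equal(annotate_variant(v(161L), gm, tg)$category, "splice_site")
  expect_equal(annotate_variant(v(162L), gm, tg)$category, "splice_site")
  expect_equal(annotate_variant(v(219L), gm, tg)$category, "splice_site")
  expect_equal(annotate_variant(v(190L), gm, tg)$category, "intron")
  expect_equal(annotate_variant(v(110L), gm, tg)$category, "utr5")
  expect_equal(annotate_variant(v(305L), gm, tg)$category, "utr3")
  expect_equal(annotate_variant(v(130L), gm, tg)$category, "missense")

  # 5 kb flank boundary: 4999 bp before the gene is upstream, 5001 not
  gm2 <- gene_model("gY.1", "gX", "+", exons = cbind(5200L, 5700L),
                    cds = cbind(5200L, 5700L))
  expect_equal(annotate_variant(v(5200L - 4999L), gm2, tg)$category,
               "upstream")
  expect_equal(annotate_variant(v(5200L - 5000L), gm2, tg)$category,
               "upstream")
  expect_equal(annotate_variant(v(199L), gm2, tg)$category, "intergenic")

  expect_error(annotate_variant(list(target = "gX", position = 130L,
                                     ref = "G", alt = "T"), gm, tg),
               "reference mismatch")
  expect_error(annotate_variant(list(target = "gX", position = 99999L,
                                     ref = "A", alt = "C"), gm, tg),
               "outside target")
})

test_that("minus-strand annotation equals plus-strand on the reverse complement", {
  set.seed(14)
  for (rep in 1:5) {
    n_codons <- sample(5:12, 1)
    cds <- paste0("ATG",
                  paste(sample(c("GCA", "CAA", "GGC", "TGG", "CTT", "AGA"),
                               n_codons, TRUE), collapse = ""), "TAA")
    pad <- 30L
    L <- 2L * pad + nchar(cds)
    # minus-strand gene: genomic sequence is the reverse complement of the cds
    rc <- gridtill:::.revcomp(cds)
    seq_minus <- paste0(strrep("A", pad), rc, strrep("A", pad))
    tg_minus <- reference_targets(c(gM = seq_minus))
    gm_minus <- gene_model("g", "gM", "-",
                           exons = cbind(pad + 1L, pad + nchar(cds)),
                           cds = cbind(pad + 1L, pad + nchar(cds)))
    # equivalent plus-strand locus
    seq_plus <- gridtill:::.revcomp(seq_minus)
    tg_plus <- reference_targets(c(gM = seq_plus))
    gm_plus <- gene_model("g", "gM", "+",
                          exons = cbind(pad + 1L, pad + nchar(cds)),
                          cds = cbind(pad + 1L, pad + nchar(cds)))
    for (k in 1:8) {
      pos <- sample(seq(pad + 1L, pad + nchar(cds)), 1)
      ref <- substr(seq_minus, pos, pos)
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
      a_minus <- annotate_variant(list(target = "gM", position = pos,
                                       ref = ref, alt = alt),
                                  gm_minus, tg_minus)
      pos2 <- L - pos + 1L
      a_plus <- annotate_variant(list(target = "gM", position = pos2,
                                      ref = gridtill:::.complement(ref),
                                      alt = gridtill:::.complement(alt)),
                                 gm_plus, tg_plus)
      expect_equal(a_minus$category, a_plus$category)
      expect_equal(a_minus$aa_change, a_plus$aa_change)
    }
  }
})

test_that("synonymous iff the translated protein is unchanged", {
  set.seed(15)
  codons <- setdiff(names(Biostrings::GENETIC_CODE),
                    c("TAA", "TAG", "TGA"))
  for (rep in 1:10) {
    cds <- paste0("ATG", paste(sample(codons, 20, TRUE), collapse = ""),
                  "TAA")
    fx <- toy_coding_gene(cds)
    for (k in 1:10) {
      pos <- sample(seq(51L, 50L + nchar(cds)), 1)
      ref <- substr(fx$targets[["gX"]], pos, pos)
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
      ann <- annotate_variant(list(target = "gX", position = pos,
                                   ref = ref, alt = alt),
                              fx$model, fx$targets)
      # independent oracle: translate the whole mutated CDS with Biostrings
      mutated <- cds
      substr(mutated, pos - 50L, pos - 50L) <- alt
      p0 <- as.character(Biostrings::translate(Biostrings::DNAString(cds)))
      p1 <- as.character(Biostrings::translate(Biostrings::DNAString(mutated)))
      expect_equal(ann$category == "synonymous", identical(p0, p1))
    }
  }
})

test_that("effect summaries partition and recover planted proportions", {
  one <- summarize_effects(data.frame(category = "missense"))
  expect_equal(one$fraction[one$category == "missense"], 1)
  expect_equal(sum(one$fraction), 1)

  # structural categories planted at known positions are recovered
  seq <- strrep("A", 20000)
  substr(seq, 8061, 8062) <- "GT"; substr(seq, 8149, 8150) <- "AG"
  tg <- reference_targets(c(gX = seq))
  gm <- gene_model("gX.1", "gX", "+",
                   exons = rbind(c(8001L, 8060L), c(8151L, 8240L)),
                   cds = rbind(c(8001L, 8060L), c(8151L, 8240L)))
  pools <- list(intron = 8065:8145, upstream = 3001:8000,
                downstream = 8241:13240, intergenic = 14000:19000)
  probs <- c(intron = 0.272, upstream = 0.15, downstream = 0.15,
             intergenic = 0.428)
  set.seed(16)
  n <- 1500
  cats <- sample(names(probs), n, TRUE, probs)
  vars <- data.frame(
    target = "gX",
    position = vapply(cats, function(cc) sample(pools[[cc]], 1), integer(1)),
    stringsAsFactors = FALSE)
  vars$ref <- vapply(vars$position, function(p) substr(seq, p, p),
                     character(1))
  vars$alt <- ifelse(vars$ref == "A", "G", "C")
  ann <- annotate_variants(vars, gm, tg)
  sm <- summarize_effects(ann)
  expect_equal(sum(sm$fraction), 1)
  for (cc in names(probs)) {
    p <- probs[[cc]]
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(sm$fraction[sm$category == cc] - p), 3 * se + 1e-12)
  }
})
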