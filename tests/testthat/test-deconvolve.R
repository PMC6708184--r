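test_that("the twice-per-block rule assigns, rejects and flags as specified", {
  ly <- build_layout(1, 16, 16)
  # one row + one column -> confirmed at the intersection
  h <- hits_for_variant(1, rows = 3, cols = 7)
  calls <- deconvolve_block(h, ly)
  expect_equal(calls$status, "confirmed")
  expect_equal(calls$plant_id, "B1R3C7")
  expect_equal(calls$zygosity, "het")  # fraction 0.031 < 3/64

  # a single-axis hit is rejected
  r <- deconvolve_block(hits_for_variant(1, rows = 3, cols = integer(0)), ly)
  expect_equal(r$status, "row_only")
  expect_true(is.na(r$plant_id))
  co <- deconvolve_block(hits_for_variant(1, rows = integer(0), cols = 5), ly)
  expect_equal(co$status, "column_only")

  # crossed intersections -> ambiguous listing all four candidates
  a <- deconvolve_block(hits_for_variant(1, rows = c(2, 5), cols = c(1, 4)), ly)
  expect_equal(a$status, "ambiguous")
  expect_setequal(strsplit(a$candidate_plants, ",")[[1]],
                  c("B1R2C1", "B1R2C4", "B1R5C1", "B1R5C4"))

  # single-axis hit with the other axis failed -> undetermined
  u <- deconvolve_block(hits_for_variant(1, rows = 3, cols = integer(0)), ly,
                        failed_pools = "B1_C12")
  expect_equal(u$status, "undetermined")

  expect_error(deconvolve_block(hits_for_variant(1, rows = 17, cols = 1), ly),
               "outside block")
  expect_error(
    deconvolve_block(rbind(hits_for_variant(1, 1, 1),
                           hits_for_variant(2, 1, 1)), ly),
    "one block at a time")
})

test_that("deconvolution matches the brute-force oracle exhaustively", {
  for (dims in list(c(1, 1), c(2, 2), c(2, 3), c(3, 3), c(4, 4))) {
    ly <- build_layout(1, dims[1], dims[2])
    rows_all <- seq_len(dims[1]); cols_all <- seq_len(dims[2])
    rsub <- lapply(0:(2^dims[1] - 1), function(m)
      rows_all[bitwAnd(m, 2^(rows_all - 1)) > 0])
    csub <- lapply(0:(2^dims[2] - 1), function(m)
      cols_all[bitwAnd(m, 2^(cols_all - 1)) > 0])
    for (R in rsub) for (C in csub) {
      h <- hits_for_variant(1, rows = R, cols = C)
      got <- deconvolve_block(h, ly)
      want <- oracle_deconvolve(ly, 1, R, C)
      if (length(R) == 0 && length(C) == 0) {
        expect_equal(nrow(got), 0)
      } else {
        expect_equal(got$status, want$status)
        if (want$status == "confirmed") {
          expect_equal(got$plant_id, want$plant)
        } else if (want$status == "ambiguous") {
          expect_equal(strsplit(got$candidate_plants, ",")[[1]],
                       want$candidates)
        }
      }
    }
  }
})

test_that("multiple variants in one block deconvolve independently", {
  ly <- build_layout(1, 4, 4)
  h <- rbind(
    hits_for_variant(1, rows = 1, cols = 2, position = 10L),
    hits_for_variant(1, rows = c(2, 3), cols = c(1, 4), position = 20L),
    hits_for_variant(1, rows = 4, cols = integer(0), position = 30L)
  )
  calls <- deconvolve_block(h, ly)
  expect_equal(nrow(calls), 3)
  expect_equal(calls$status[calls$position == 10], "confirmed")
  expect_equal(calls$status[calls$position == 20], "ambiguous")
  expect_equal(calls$status[calls$position == 30], "row_only")
  # spot-check against the oracle
  for (cs in list(list(p = 10L, R = 1, C = 2),
                  list(p = 20L, R = c(2, 3), C = c(1, 4)),
                  list(p = 30L, R = 4, C = integer(0)))) {
    want <- oracle_deconvolve(ly, 1, cs$R, cs$C)
    expect_equal(calls$status[calls$position == cs$p], want$status)
  }
})

test_that("zygosity follows the pooled-fraction boundary with het ties", {
  zp <- zygosity_params(16)
  expect_equal(zp$het_expected, 1 / 32)
  expect_equal(zp$hom_expected, 1 / 16)
  expect_equal(zp$boundary, 3 / 64)
  expect_true(zp$het_expected < zp$boundary && zp$boundary < zp$hom_expected)

  expect_equal(infer_zygosity(0.028, 0.029, zp), "het")
  expect_equal(infer_zygosity(0.0625, 0.0625, zp), "hom")
  expect_equal(infer_zygosity(3 / 64, 3 / 64, zp), "het")  # tie rule
  # depth weighting pulls the mean toward the deeper pool
  expect_equal(infer_zygosity(0.03, 0.09, zp, row_depth = 10000,
                              col_depth = 100), "het")
  expect_error(infer_zygosity(0, 0.03, zp), "\\(0, 1\\)")
})

test_that("duplicate collapse merges sibling calls and is idempotent", {
  # 23 distinct variants: one carried by 5 plants, three by 2, 19 unique
  mk <- function(i, plants) {
    data.frame(target = "g1", position = 1000L + i, ref = "C", alt = "T",
               plant_id = plants, status = "confirmed",
               stringsAsFactors = FALSE)
  }
  calls <- rbind(
    mk(1, sprintf("B%dR1C1", 1:5)),
    mk(2, sprintf("B%dR2C2", 1:2)),
    mk(3, sprintf("B%dR3C3", 1:2)),
    mk(4, sprintf("B%dR4C4", 1:2)),
    do.call(rbind, lapply(5:23, function(i) mk(i, sprintf("B1R%dC5", i))))
  )
  expect_equal(nrow(calls), 30)
  ind <- collapse_duplicates(calls)
  expect_equal(nrow(ind), 23)
  expect_equal(sort(ind$n_carriers, decreasing = TRUE)[1:4], c(5, 2, 2, 2))
  expect_equal(collapse_duplicates(ind), ind)  # idempotent

  expect_equal(nrow(collapse_duplicates(mk(9, sprintf("p%d", 1:3)))), 1)
  five <- do.call(rbind, lapply(1:5, function(i) mk(i, "p1")))
  expect_equal(nrow(collapse_duplicates(five)), 5)
})

test_that("scoring against truth counts pairs correctly", {
  tg <- reference_targets(c(g1 = strrep("G", 50)))
  mut <- data.frame(plant_id = c("B1R1C1", "B1R2C2"), target = "g1",
                    position = c(10L, 20L), ref = "G", alt = "A",
                    zygosity = c("het", "hom"), stringsAsFactors = FALSE)
  pop <- make_population(mut, c("B1R1C1", "B1R2C2"), tg)
  perfect <- data.frame(target = "g1", position = c(10L, 20L), ref = "G",
                        alt = "A", plant_id = c("B1R1C1", "B1R2C2"),
                        status = "confirmed", zygosity = c("het", "hom"),
                        stringsAsFactors = FALSE)
  ev <- evaluate_against_truth(perfect, pop)
  expect_equal(ev$sensitivity, 1)
  expect_equal(ev$fdr, 0)
  expect_equal(ev$zygosity_accuracy, 1)

  none <- evaluate_against_truth(perfect[0, ], pop)
  expect_equal(none$sensitivity, 0)
  expect_equal(none$fdr, 0)
  expect_false(none$fdr_defined)

  half <- evaluate_against_truth(perfect[1, ], pop)
  expect_equal(half$sensitivity, 0.5)
  wrong <- perfect
  wrong$plant_id[2] <- "B1R9C9"
  expect_equal(evaluate_against_truth(wrong, pop)$fdr, 0.5)
})
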