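th <- class_thresholds()

row_class <- function(ccm_fc, ccm_p, ag_fc, ag_p) {
  ccm <- tibble::tibble(gene = "g", log2fc = ccm_fc, padj = ccm_p)
  aging <- tibble::tibble(gene = "g", log2fc = ag_fc, padj = ag_p)
  as.character(classify_regulation(ccm, aging, th)$regulation_class)
}

test_that("single-gene classification follows the threshold rules", {
  # a CCM-downregulated peptidase gene that trends upward with aging
  expect_equal(row_class(-0.90, 3.70e-13, 0.20, 2.38e-01), "opposite")
  expect_equal(row_class(-0.5, 0.5, 0.4, 0.01), "not_ccm_significant")
  expect_equal(row_class(-0.5, 0.01, -0.4, 0.2), "trend_same")
  expect_equal(row_class(-0.5, 0.01, -0.4, 0.05), "convergent")
  expect_equal(row_class(-0.5, 0.01, -0.4, 0.35), "unclassified")
  expect_equal(row_class(-0.5, 0.01, 0.4, NA), "unclassified")
})

test_that("padj boundaries are half-open as documented", {
  expect_equal(row_class(-0.5, 0.01, -0.4, 0.1), "trend_same")   # exactly 0.1
  expect_equal(row_class(-0.5, 0.01, -0.4, 0.3), "unclassified") # exactly 0.3
  expect_equal(row_class(-0.5, 0.01, 0.4, 0.3), "unclassified")
  expect_equal(row_class(-0.5, 0.1, 0.4, 0.01), "not_ccm_significant") # ccm at 0.1
})

test_that("zero fold change cannot be signed and warns", {
  expect_warning(cls <- row_class(0, 0.01, 0.4, 0.01), "log2FC exactly 0")
  expect_equal(cls, "unclassified")
})

test_that("the bundled opposite-regulation tables give 12 down and 4 up", {
  ccm <- read_de_table(example_de_table("ccm"))
  aging <- read_de_table(example_de_table("aging"))
  classified <- classify_regulation(ccm, aging)
  expect_true(all(classified$regulation_class == "opposite"))
  counts <- regulation_counts(classified)
  expect_equal(counts$n[counts$regulation_class == "opposite" &
                          counts$ccm_direction == "down"], 12L)
  expect_equal(counts$n[counts$regulation_class == "opposite" &
                          counts$ccm_direction == "up"], 4L)
})

test_that("empty tables, duplicates and one-sided genes are handled", {
  empty <- tibble::tibble(gene = character(0), log2fc = numeric(0),
                          padj = numeric(0))
  out <- classify_regulation(empty, empty)
  expect_equal(nrow(out), 0)
  expect_true(all(regulation_counts(out)$n == 0))

  dup <- tibble::tibble(gene = c("a", "a"), log2fc = c(1, 2), padj = c(0.1, 0.2))
  expect_error(classify_regulation(dup, empty), "duplicate.*ccm")

  one_sided <- classify_regulation(
    tibble::tibble(gene = "x", log2fc = -1, padj = 0.001), empty)
  expect_equal(as.character(one_sided$regulation_class), "unclassified")
})

test_that("classification matches an independent oracle on random tables", {
  set.seed(14)
  n <- 200
  genes <- sprintf("g%03d", 1:n)
  ccm <- tibble::tibble(gene = genes,
                        log2fc = round(rnorm(n, 0, 0.6), 2),
                        padj = ifelse(runif(n) < 0.1, NA, round(runif(n)^2, 4)))
  aging <- tibble::tibble(gene = sample(genes, 180),
                          log2fc = round(rnorm(180, 0, 0.6), 2),
                          padj = round(runif(180), 4))
  got <- classify_regulation(ccm, aging, th)
  expected <- vapply(seq_len(nrow(got)), function(i) {
    classify_oracle(got$ccm_log2fc[i], got$ccm_padj[i],
                    got$aging_log2fc[i], got$aging_padj[i])
  }, character(1))
  expect_equal(as.character(got$regulation_class), expected)
  # classes partition: every gene has exactly one class
  expect_false(anyNA(got$regulation_class))
  expect_equal(nrow(got), n)
})

test_that("classification is invariant to row order and joint sign flips", {
  ccm <- read_de_table(example_de_table("ccm"))
  aging <- read_de_table(example_de_table("aging"))
  base <- classify_regulation(ccm, aging)
  shuf <- classify_regulation(ccm[rev(seq_len(nrow(ccm))), ], aging)
  expect_equal(dplyr::arrange(base, gene), dplyr::arrange(shuf, gene))
  flipped <- classify_regulation(dplyr::mutate(ccm, log2fc = -log2fc),
                                 dplyr::mutate(aging, log2fc = -log2fc))
  expect_equal(as.character(flipped$regulation_class),
               as.character(base$regulation_class))
})

test_that("fold-change correlation matches the rank-then-Pearson oracle", {
  set.seed(3)
  a <- tibble::tibble(gene = sprintf("g%02d", 1:20), log2fc = rnorm(20))
  expect_equal(fc_correlation(a, a)$rho, 1)
  expect_equal(fc_correlation(a, dplyr::mutate(a, log2fc = -log2fc))$rho, -1)
  b <- tibble::tibble(gene = a$gene, log2fc = rnorm(20))
  got <- fc_correlation(a, b)
  expect_equal(got$rho, cor(rank(a$log2fc), rank(b$log2fc)), tolerance = 1e-12)
  expect_equal(got$n, 20L)
  pear <- fc_correlation(a, b, method = "pearson")
  expect_equal(pear$rho, cor(a$log2fc, b$log2fc), tolerance = 1e-12)
  expect_error(fc_correlation(a[1:3, ], b), "at least 4")
  sub <- fc_correlation(a, b, genes = a$gene[1:10])
  expect_equal(sub$n, 10L)
})
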